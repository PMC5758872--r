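#' Is the external Turner-parameter folding engine available?
#'
#' The `"turner"` backend of [energy_model()] delegates ensemble free
#' energies to the `RNAfold` executable (ViennaRNA). This checks for it on
#' the PATH.
#'
#' @return logical.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

rnafold_ensemble_dG <- function(seq, constraint = NULL, celsius = 37) {
  if (!rnafold_available()) {
    stop("RNAfold executable not found on PATH; the turner backend needs it")
  }
  args <- c("-p", "--noPS", "-T", format(celsius))
  input <- seq
  if (!is.null(constraint)) {
    args <- c(args, "-C", "--enforceConstraint")
    input <- c(seq, constraint)
  }
  out <- suppressWarnings(system2("RNAfold", args, input = input,
                                  stdout = TRUE, stderr = TRUE))
  m <- regmatches(out, regexpr("\\[\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\]", out))
  m <- m[nzchar(m)]
  if (length(m) == 0L) {
    stop("could not parse RNAfold ensemble free energy from output:\n",
         paste(out, collapse = "\n"))
  }
  as.numeric(gsub("[][ ]", "", m[[1L]]))
}

pairs_to_constraint <- function(n, pairs) {
  c <- rep(".", n)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.matrix(pairs)
    c[pairs[, 1L] + 1L] <- "("
    c[pairs[, 2L] + 1L] <- ")"
  }
  paste(c, collapse = "")
}

# p(substructure) = Z_constrained / Z = exp(-(G_c - G) / RT) from the two
# ensemble free energies reported by RNAfold.
turner_constrained_probability <- function(seq, required_pairs, model) {
  celsius <- model$temperature - 273.15
  g_tot <- rnafold_ensemble_dG(seq, NULL, celsius)
  if (is.null(required_pairs) || NROW(required_pairs) == 0L) return(1.0)
  g_con <- rnafold_ensemble_dG(seq,
                               pairs_to_constraint(nchar(seq), required_pairs),
                               celsius)
  RT <- model$R * model$temperature
  min(1.0, exp(-(g_con - g_tot) / RT))
}
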