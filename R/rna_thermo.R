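#' @useDynLib dletools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GAS_CONSTANT <- 1.9872e-3  # kcal/(mol K)
MIN_HAIRPIN_LOOP <- 3L     # steric minimum unpaired nt enclosed by a pair

#' Construct an RNA folding energy model
#'
#' The `"simple"` backend scores a secondary structure as the sum of its
#' base-pair energies (no stacking or loop terms) and is exactly computable
#' and enumerable, so every probability it reports can be verified by
#' exhaustive enumeration on short sequences. The `"turner"` backend
#' delegates ensemble free energies to an external `RNAfold` executable
#' (nearest-neighbor parameters) and is intended for runs on natural
#' sequences where fidelity to full thermodynamics matters.
#'
#' @param backend `"simple"` or `"turner"`.
#' @param pair_energies named numeric, kcal/mol for `GC`, `AU`, `GU` pairs
#'   (simple backend). Defaults -3, -2, -1; must satisfy
#'   `GC <= AU <= GU < 0`.
#' @param temperature temperature in kelvin (default 310.15 K = 37 C).
#' @param allow_GU permit G.U wobble pairs (default TRUE).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(backend = c("simple", "turner"),
                         pair_energies = c(GC = -3.0, AU = -2.0, GU = -1.0),
                         temperature = 310.15, allow_GU = TRUE) {
  backend <- match.arg(backend)
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_energies)),
            temperature > 0)
  e <- pair_energies[c("GC", "AU", "GU")]
  if (!(e["GC"] <= e["AU"] && e["AU"] <= e["GU"] && e["GU"] < 0)) {
    stop("pair energies must satisfy GC <= AU <= GU < 0")
  }
  structure(list(backend = backend, pair_energies = e,
                 temperature = temperature, R = GAS_CONSTANT,
                 allow_GU = isTRUE(allow_GU)),
            class = "energy_model")
}

model_at_temperature <- function(model, kelvin) {
  model$temperature <- kelvin
  model
}

celsius_to_kelvin <- function(tc) tc + 273.15

encode_rna <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  if (anyNA(v)) stop("invalid alphabet in sequence (expected A/C/G/U)")
  v - 1L  # 0-based: A=0, C=1, G=2, U=3
}

# 4x4 matrix of log Boltzmann weights per (5' base, 3' base); -Inf where
# the two bases cannot pair under the model.
log_weight_matrix <- function(model) {
  RT <- model$R * model$temperature
  e <- model$pair_energies
  m <- matrix(-Inf, 4L, 4L, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  m["G", "C"] <- m["C", "G"] <- -e[["GC"]] / RT
  m["A", "U"] <- m["U", "A"] <- -e[["AU"]] / RT
  if (model$allow_GU) m["G", "U"] <- m["U", "G"] <- -e[["GU"]] / RT
  m
}

#' Can two bases pair under a model's pairing rule?
#' @param a,b single characters in A/C/G/U.
#' @param allow_GU permit G.U wobble.
#' @return logical.
#' @export
can_pair <- function(a, b, allow_GU = TRUE) {
  p <- paste0(a, b)
  p %in% c("GC", "CG", "AU", "UA") || (allow_GU && p %in% c("GU", "UG"))
}

# Validate a set of (i, j) pairs (0-based, i < j): bounds, min loop,
# complementarity, uniqueness of indices, nestedness.
validate_pairs <- function(seq, pairs, model, what = "required pair") {
  if (is.null(pairs) || NROW(pairs) == 0L) return(invisible(NULL))
  pairs <- as.matrix(pairs)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (i < 0L || j >= n || i >= j) stop(what, " (", i, ",", j, ") out of bounds")
    if (j - i - 1L < MIN_HAIRPIN_LOOP) {
      stop(what, " (", i, ",", j, ") violates the minimum hairpin loop of ",
           MIN_HAIRPIN_LOOP, " nt")
    }
    if (!can_pair(ch[i + 1L], ch[j + 1L], model$allow_GU)) {
      stop(what, " (", i, ",", j, "): ", ch[i + 1L], "-", ch[j + 1L],
           " is not pairable under this model")
    }
  }
  idx <- c(pairs[, 1L], pairs[, 2L])
  if (anyDuplicated(idx)) stop(what, "s share a position")
  if (nrow(pairs) > 1L) {
    for (r in seq_len(nrow(pairs) - 1L)) {
      for (q in (r + 1L):nrow(pairs)) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        k <- pairs[q, 1L]; l <- pairs[q, 2L]
        crossing <- (i < k && k < j && j < l) || (k < i && i < l && l < j)
        if (crossing) stop(what, "s (", i, ",", j, ") and (", k, ",", l, ") cross")
      }
    }
  }
  invisible(NULL)
}

forced_vector <- function(n, pairs) {
  f <- rep(-1L, n)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    pairs <- as.matrix(pairs)
    f[pairs[, 1L] + 1L] <- as.integer(pairs[, 2L])
    f[pairs[, 2L] + 1L] <- as.integer(pairs[, 1L])
  }
  f
}

#' Total partition function of a sequence
#'
#' Boltzmann-weighted sum over all nested secondary structures (Watson-Crick
#' plus, optionally, G.U pairs; minimum hairpin loop 3 nt), including the
#' open chain at energy 0, so the result is always >= 1. Computed by dynamic
#' programming in log space.
#'
#' @param seq RNA string over A/C/G/U.
#' @param model an [energy_model()] with `backend = "simple"`.
#' @param log return log(Z) instead of Z (safe for long sequences).
#' @return numeric scalar Z (or log Z).
#' @export
partition_function <- function(seq, model = energy_model(), log = FALSE) {
  if (model$backend != "simple") {
    stop("partition_function is defined for the simple backend; the turner ",
         "backend only exposes ensemble probabilities")
  }
  seq <- normalize_rna(seq)
  lz <- pf_log_z_cpp(encode_rna(seq), log_weight_matrix(model),
                     rep(-1L, nchar(seq)), MIN_HAIRPIN_LOOP)
  if (log) lz else exp(lz)
}

#' Probability that a fixed set of base pairs forms in the ensemble
#'
#' Computes the constrained partition function summing only structures that
#' contain every required pair, and reports `p = Z_constrained / Z_total`.
#' An impossible constraint (non-complementary or crossing pairs) is an
#' error, distinct from a legal-but-unfavorable constraint which simply has
#' small p.
#'
#' @param seq RNA string.
#' @param required_pairs 2-column matrix of 0-based (i, j) pairs, i < j;
#'   `NULL` or empty means unconstrained (p = 1).
#' @param model an [energy_model()]. With the `"turner"` backend the
#'   two ensemble free energies are obtained from `RNAfold` and
#'   `p = exp(-(G_constrained - G_total) / RT)`; Z values are then reported
#'   as `NA`.
#' @return list of class `fold_result`: `Z_total`, `Z_constrained`,
#'   `p_substructure`, `temperature` (kelvin).
#' @export
constrained_probability <- function(seq, required_pairs = NULL,
                                    model = energy_model()) {
  seq <- normalize_rna(seq)
  validate_pairs(seq, required_pairs, model)
  if (model$backend == "turner") {
    p <- turner_constrained_probability(seq, required_pairs, model)
    return(structure(list(Z_total = NA_real_, Z_constrained = NA_real_,
                          p_substructure = p,
                          temperature = model$temperature),
                     class = "fold_result"))
  }
  si <- encode_rna(seq)
  lw <- log_weight_matrix(model)
  lz <- pf_log_z_cpp(si, lw, rep(-1L, nchar(seq)), MIN_HAIRPIN_LOOP)
  lzc <- if (is.null(required_pairs) || NROW(required_pairs) == 0L) {
    lz
  } else {
    pf_log_z_cpp(si, lw, forced_vector(nchar(seq), required_pairs),
                 MIN_HAIRPIN_LOOP)
  }
  structure(list(Z_total = exp(lz), Z_constrained = exp(lzc),
                 p_substructure = exp(lzc - lz),
                 temperature = model$temperature),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> p =", format(x$p_substructure, digits = 6),
      "at", x$temperature, "K\n")
  invisible(x)
}

#' Substructure probability across a temperature grid
#'
#' @param seq RNA string.
#' @param required_pairs 0-based pair matrix as in
#'   [constrained_probability()].
#' @param model an [energy_model()]; its temperature field is replaced by
#'   each grid point.
#' @param t_grid_celsius numeric vector of temperatures in degrees Celsius
#'   (converted to kelvin internally); default 25-28 C, the range at which
#'   zebrafish embryos are commonly reared.
#' @return data.frame with columns `T_celsius`, `p`.
#' @export
probability_vs_temperature <- function(seq, required_pairs = NULL,
                                       model = energy_model(),
                                       t_grid_celsius = 25:28) {
  stopifnot(length(t_grid_celsius) > 0, all(t_grid_celsius > -273.15))
  p <- vapply(t_grid_celsius, function(tc) {
    constrained_probability(
      seq, required_pairs,
      model_at_temperature(model, celsius_to_kelvin(tc)))$p_substructure
  }, 0.0)
  data.frame(T_celsius = as.numeric(t_grid_celsius), p = p)
}

#' Exact base-pair probability matrix (simple backend)
#'
#' `p[i+1, j+1]` is the ensemble probability that positions i and j
#' (0-based, i < j) are paired. Computed by the inside-outside method on
#' the same recursion as [partition_function()]; exact for the simple
#' energy model.
#'
#' @param seq RNA string.
#' @param model an [energy_model()] with `backend = "simple"`.
#' @return n x n numeric matrix, upper triangle populated.
#' @export
bp_probability_matrix <- function(seq, model = energy_model()) {
  if (model$backend != "simple") stop("base-pair matrices require the simple backend")
  seq <- normalize_rna(seq)
  bp_prob_cpp(encode_rna(seq), log_weight_matrix(model), MIN_HAIRPIN_LOOP)
}

## ---- exhaustive enumeration (reference implementation) ----

#' Enumerate every nested secondary structure of a short sequence
#'
#' Reference implementation by explicit recursion; intended for validating
#' the dynamic-programming routines on short sequences (the structure count
#' grows exponentially). Returns each structure as a 2-column 0-based pair
#' matrix (the open chain is the 0-row matrix).
#'
#' @param seq RNA string.
#' @param allow_GU permit G.U wobble pairs.
#' @return list of pair matrices.
#' @export
enumerate_structures <- function(seq, allow_GU = TRUE) {
  seq <- normalize_rna(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(), 0L, 2L)))
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)  # i unpaired
    ks <- seq_len(0L)
    if (j >= i + MIN_HAIRPIN_LOOP + 1L) ks <- (i + MIN_HAIRPIN_LOOP + 1L):j
    for (k in ks) {
      if (!can_pair(ch[i + 1L], ch[k + 1L], allow_GU)) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (s1 in left) for (s2 in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(0L, n - 1L)
}

#' Partition function and constrained probability by exhaustive enumeration
#'
#' Independent reference for [partition_function()] and
#' [constrained_probability()]: enumerates all structures, scores each as
#' the sum of its pair energies, Boltzmann-sums, and (optionally) filters
#' to structures containing every required pair by explicit membership.
#'
#' @param seq RNA string.
#' @param model simple-backend [energy_model()].
#' @param required_pairs optional 0-based pair matrix.
#' @return list: `Z_total`, `Z_constrained`, `p_substructure`, `n_structures`.
#' @export
enum_partition_function <- function(seq, model = energy_model(),
                                    required_pairs = NULL) {
  seq <- normalize_rna(seq)
  ch <- strsplit(seq, "")[[1]]
  RT <- model$R * model$temperature
  e <- model$pair_energies
  pair_energy <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(e[["GC"]])
    if (p %in% c("AU", "UA")) return(e[["AU"]])
    e[["GU"]]
  }
  structs <- enumerate_structures(seq, allow_GU = model$allow_GU)
  weights <- vapply(structs, function(s) {
    if (nrow(s) == 0L) return(1.0)
    en <- sum(vapply(seq_len(nrow(s)), function(r) {
      pair_energy(ch[s[r, 1L] + 1L], ch[s[r, 2L] + 1L])
    }, 0.0))
    exp(-en / RT)
  }, 0.0)
  Z <- sum(weights)
  if (is.null(required_pairs) || NROW(required_pairs) == 0L) {
    Zc <- Z
  } else {
    req <- as.matrix(required_pairs)
    keep <- vapply(structs, function(s) {
      if (nrow(s) < nrow(req)) return(FALSE)
      have <- paste(s[, 1L], s[, 2L])
      all(paste(req[, 1L], req[, 2L]) %in% have)
    }, FALSE)
    Zc <- sum(weights[keep])
  }
  list(Z_total = Z, Z_constrained = Zc, p_substructure = Zc / Z,
       n_structures = length(structs))
}
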