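# Independent oracles used across the suite. These deliberately re-derive
# results by the most literal method available (nested loops, explicit
# checks) rather than sharing code with the implementation under test.

# brute-force composite-grammar matcher: tests every (anchor, spacer,
# stem, loop) decomposition independently with direct predicate checks
oracle_dle <- function(seq, d, region_start = 0L, region_end = nchar(seq)) {
  ch <- strsplit(seq, "")[[1]]
  pairable <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AU", "UA", "GC", "CG") ||
      (d$allow_GU && p %in% c("GU", "UG"))
  }
  la <- nchar(d$anchor)
  out <- list()
  for (a in region_start:(region_end - 1L)) {
    if (a + la > region_end) next
    if (substr(seq, a + 1L, a + la) != d$anchor) next
    if (d$require_preceding_A && (a < 1L || ch[a] != "A")) next
    for (s in d$spacer_min:d$spacer_max) {
      sp <- substr(seq, a + la + 1L, a + la + s)
      if (d$spacer_alphabet == "pyrimidine" && s > 0L &&
          !all(strsplit(sp, "")[[1]] %in% c("U", "C"))) next
      for (b in d$stem_min_bp:d$stem_max_bp) {
        for (L in d$loop_min:d$loop_max) {
          p0 <- a + la + s
          e3 <- p0 + 2L * b + L
          if (e3 > region_end) next
          ok <- TRUE
          for (k in 0L:(b - 1L)) {
            if (!pairable(ch[p0 + k + 1L], ch[p0 + b + L + b - k])) {
              ok <- FALSE; break
            }
          }
          if (ok) {
            out[[length(out) + 1L]] <- c(anchor = a, spacer_len = s,
                                         stem_bp = b, loop_len = L)
          }
        }
      }
    }
  }
  out
}

# decomposition key for set comparison
decomp_key <- function(h) {
  paste(h$anchor[1L], iv_len(h$spacer), nrow(h$pairs),
        h$loop[2L] - h$loop[1L], sep = "_")
}
oracle_key <- function(o) paste(o["anchor"], o["spacer_len"], o["stem_bp"],
                                o["loop_len"], sep = "_")

# brute-force maximal repeat-run finder scanning every offset
oracle_repeats <- function(seq, unit, min_units) {
  n <- nchar(seq); ul <- nchar(unit)
  runs <- list()
  i <- 1L
  while (i <= n - ul * min_units + 1L) {
    k <- 0L
    while (i + (k + 1L) * ul - 1L <= n &&
           substr(seq, i + k * ul, i + (k + 1L) * ul - 1L) == unit) {
      k <- k + 1L
    }
    if (k >= min_units) {
      # maximality on the left: preceding unit must not match
      left_ok <- i - ul < 1L ||
        substr(seq, i - ul, i - 1L) != unit
      if (left_ok) {
        runs[[length(runs) + 1L]] <- c(start = i - 1L, n_units = k)
      }
      i <- i + k * ul
    } else {
      i <- i + 1L
    }
  }
  runs
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# fixture sequences for folding-oracle equivalence (all <= 14 nt)
fold_fixture_set <- function() {
  set.seed(101)
  hand <- c("AAAA", "GAAAC", "GGGAAAACCC", "GCGCAAAGCGC", "ACGUACGUACGUAC",
            "UUUUGGGGAAAACC", "GUGUGAAAACACAC")
  rand <- vapply(5:14, function(n) random_rna(n), "")
  c(hand, rand)
}
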