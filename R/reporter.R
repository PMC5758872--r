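#' Maximum-intensity projection of an in-focus window
#'
#' Selects the contiguous window of `window` slices with the largest total
#' intensity (the automated stand-in for choosing slices "in sharp focus"
#' by eye; leftmost window on ties, or set `slices` to override) and
#' returns the elementwise maximum over it.
#'
#' @param stack numeric 3-D array `[y, x, z]` or list of matrices.
#' @param window number of consecutive slices (default 4).
#' @param slices optional manual override, integer `c(first, last)`
#'   (1-based inclusive).
#' @return 2-D matrix with attribute `window = c(first, last)`.
#' @export
project <- function(stack, window = 4L, slices = NULL) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3L || dim(stack)[3L] < 1L) {
    stop("stack must be a non-empty z-stack")
  }
  nz <- dim(stack)[3L]
  if (is.null(slices)) {
    if (window > nz) stop("window (", window, ") exceeds slice count (", nz, ")")
    totals <- apply(stack, 3L, sum)
    wsum <- vapply(seq_len(nz - window + 1L),
                   function(s) sum(totals[s:(s + window - 1L)]), 0.0)
    s <- which.max(wsum)
    slices <- c(s, s + window - 1L)
  } else {
    stopifnot(length(slices) == 2L, slices[1L] >= 1L, slices[2L] <= nz,
              slices[1L] <= slices[2L])
  }
  plane <- apply(stack[, , slices[1L]:slices[2L], drop = FALSE], c(1L, 2L), max)
  attr(plane, "window") <- as.integer(slices)
  plane
}

#' Threshold segmentation of the blastoderm ROI
#'
#' Thresholds the (rhodamine) plane -- Otsu's method by default, or a fixed
#' value -- and keeps the largest connected component.
#'
#' @param plane 2-D intensity matrix.
#' @param threshold optional fixed threshold; default Otsu on the plane's
#'   intensity range.
#' @return logical mask matrix. Errors with class `dle_empty_roi` if no
#'   suprathreshold pixels exist.
#' @export
segment_roi <- function(plane, threshold = NULL) {
  if (length(plane) == 0L) stop("empty plane")
  if (is.null(threshold)) {
    rng <- range(plane)
    if (diff(rng) <= 0) {
      stop(structure(class = c("dle_empty_roi", "error", "condition"),
                     list(message = "uniform plane: no segmentable signal",
                          call = sys.call())))
    }
    scaled <- (plane - rng[1L]) / diff(rng)
    threshold <- rng[1L] + EBImage::otsu(EBImage::Image(scaled),
                                         range = c(0, 1)) * diff(rng)
  }
  bin <- plane > threshold
  if (!any(bin)) {
    stop(structure(class = c("dle_empty_roi", "error", "condition"),
                   list(message = "no suprathreshold pixels",
                        call = sys.call())))
  }
  lbl <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lbl <- EBImage::imageData(lbl)
  counts <- tabulate(lbl[lbl > 0])
  matrix(lbl == which.max(counts), nrow(plane), ncol(plane))
}

# background means from un-injected controls: same projection+segmentation
# pipeline; controls without segmentable signal fall back to a centered
# rectangle covering a quarter of the frame
control_background <- function(controls, window = 4L) {
  stopifnot(length(controls) >= 1L)
  bg <- vapply(controls, function(ctrl) {
    rfp_p <- project(ctrl$rfp, window)
    gfp_p <- project(ctrl$gfp, window, slices = attr(rfp_p, "window"))
    mask <- tryCatch(segment_roi(rfp_p), dle_empty_roi = function(e) NULL)
    if (is.null(mask)) {
      d <- dim(rfp_p)
      ys <- seq(floor(d[1L] / 4) + 1L, floor(3 * d[1L] / 4))
      xs <- seq(floor(d[2L] / 4) + 1L, floor(3 * d[2L] / 4))
      mask <- matrix(FALSE, d[1L], d[2L]); mask[ys, xs] <- TRUE
    }
    c(gfp = mean(gfp_p[mask]), rfp = mean(rfp_p[mask]))
  }, c(gfp = 0.0, rfp = 0.0))
  rowMeans(bg)
}

#' Measure one embryo's background-subtracted GFP/RFP ratio
#'
#' The quantification pipeline: project both channels over the in-focus
#' window chosen on the rhodamine channel, segment the blastoderm ROI on
#' the rhodamine projection, take ROI means per channel, subtract the
#' background means obtained by running the same pipeline on un-injected
#' control stacks, and normalize:
#' `ratio = (mean_gfp - bg_gfp) / (mean_rfp - bg_rfp)`.
#' An embryo with a non-positive background-subtracted rhodamine signal, or
#' with no segmentable ROI, is returned flagged (`valid = FALSE`) rather
#' than silently dropped.
#'
#' @param embryo list with `embryo_id`, `group`, `stage`, `gfp`, `rfp`
#'   (3-D arrays of identical shape).
#' @param controls list of control stacks (same fields; un-injected).
#' @param window projection window (default 4 slices).
#' @return one-row data.frame: id, group, stage, roi_area, raw and
#'   background means, ratio, valid flag and a note.
#' @export
measure <- function(embryo, controls, window = 4L) {
  stopifnot(identical(dim(embryo$gfp), dim(embryo$rfp)))
  bgm <- control_background(controls, window)
  rfp_p <- project(embryo$rfp, window)
  gfp_p <- project(embryo$gfp, window, slices = attr(rfp_p, "window"))
  row <- data.frame(embryo_id = embryo$embryo_id, group = embryo$group,
                    stage = embryo$stage, roi_area = NA_integer_,
                    mean_gfp = NA_real_, mean_rfp = NA_real_,
                    bg_gfp = bgm[["gfp"]], bg_rfp = bgm[["rfp"]],
                    ratio = NA_real_, valid = FALSE, note = "",
                    stringsAsFactors = FALSE)
  mask <- tryCatch(segment_roi(rfp_p), dle_empty_roi = function(e) NULL)
  if (is.null(mask)) {
    row$note <- "no segmentable ROI"
    return(row)
  }
  row$roi_area <- sum(mask)
  row$mean_gfp <- mean(gfp_p[mask])
  row$mean_rfp <- mean(rfp_p[mask])
  denom <- row$mean_rfp - row$bg_rfp
  if (denom <= 0) {
    row$note <- "non-positive background-subtracted rhodamine signal"
    return(row)
  }
  row$ratio <- (row$mean_gfp - row$bg_gfp) / denom
  row$valid <- TRUE
  row
}

#' Measure a cohort of embryos against shared controls
#'
#' @param embryos list of embryo stacks (see [measure()]).
#' @param controls list of control stacks.
#' @param window projection window.
#' @return data.frame, one row per embryo; invalid embryos flagged.
#' @export
measure_cohort <- function(embryos, controls, window = 4L) {
  do.call(rbind, lapply(embryos, measure, controls = controls, window = window))
}

#' Read a multi-page TIFF z-stack as a 3-D array
#' @param path TIFF path (16-bit planes).
#' @return numeric array `[y, x, z]` in raw intensity counts (0-65535).
#' @export
read_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  simplify2array(planes) * 65535
}

#' Quantify a cohort described by a sample sheet
#'
#' The sample sheet is a TSV with columns `embryo_id`, `group`, `stage`,
#' `gfp_path`, `rfp_path`, `is_control` (TRUE/FALSE); paths are resolved
#' relative to `dir`. Control rows supply the background.
#'
#' @param sheet_path sample sheet TSV.
#' @param dir directory against which image paths are resolved (default:
#'   the sheet's directory).
#' @param window projection window.
#' @return measurements data.frame from [measure_cohort()].
#' @export
quantify_cohort <- function(sheet_path, dir = dirname(sheet_path), window = 4L) {
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "group", "stage", "gfp_path", "rfp_path", "is_control")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  load_row <- function(r) {
    list(embryo_id = r$embryo_id, group = r$group, stage = r$stage,
         gfp = read_stack(file.path(dir, r$gfp_path)),
         rfp = read_stack(file.path(dir, r$rfp_path)))
  }
  rows <- split(sheet, seq_len(nrow(sheet)))
  ctrl <- lapply(rows[sheet$is_control], load_row)
  emb <- lapply(rows[!sheet$is_control], load_row)
  if (length(ctrl) == 0L) stop("sample sheet contains no control embryos")
  measure_cohort(emb, ctrl, window)
}

#' Two-way ANOVA with Bonferroni per-stage contrasts
#'
#' Fits `ratio ~ group * stage` on the valid measurements and reports the
#' ANOVA table plus per-stage pairwise group contrasts using the pooled
#' residual variance, Bonferroni-adjusted over all contrasts (the
#' Prism-style post hoc used for reporter comparisons), at `alpha`.
#'
#' @param measurements data.frame with `ratio`, `group`, `stage` and
#'   optionally `valid` (invalid rows are excluded with a message).
#' @param alpha significance level (default 0.05).
#' @return list of class `group_stats`: `anova` (term, df, F, p),
#'   `contrasts` (stage, groups, estimate, t, df, p, p_bonferroni,
#'   significant), `n_excluded`.
#' @export
compare_groups <- function(measurements, alpha = 0.05) {
  m <- measurements
  if ("valid" %in% names(m)) {
    n_exc <- sum(!m$valid)
    if (n_exc > 0L) message(n_exc, " flagged measurement(s) excluded")
    m <- m[m$valid, , drop = FALSE]
  } else n_exc <- 0L
  m$group <- factor(m$group); m$stage <- factor(m$stage)
  if (nlevels(m$group) < 2L || nlevels(m$stage) < 2L) {
    stop("need at least 2 groups and 2 stages")
  }
  cells <- table(m$group, m$stage)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1L, ]
    stop("cell (group=", rownames(cells)[bad[1L]], ", stage=",
         colnames(cells)[bad[2L]], ") has fewer than 2 embryos")
  }
  fit <- stats::aov(ratio ~ group * stage, data = m)
  an <- summary(fit)[[1L]]
  anova_tab <- data.frame(term = trimws(rownames(an)), df = an[["Df"]],
                          F = an[["F value"]], p = an[["Pr(>F)"]],
                          stringsAsFactors = FALSE)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  pairs <- utils::combn(levels(m$group), 2L, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(levels(m$stage), function(st) {
    do.call(rbind, lapply(pairs, function(pr) {
      x1 <- m$ratio[m$group == pr[1L] & m$stage == st]
      x2 <- m$ratio[m$group == pr[2L] & m$stage == st]
      est <- mean(x1) - mean(x2)
      se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      tval <- est / se
      data.frame(stage = st, groups = paste(pr, collapse = " - "),
                 estimate = est, t = tval, df = df_res,
                 p = 2 * stats::pt(-abs(tval), df_res),
                 stringsAsFactors = FALSE)
    }))
  }))
  contrasts$p_bonferroni <- pmin(1, contrasts$p * nrow(contrasts))
  contrasts$significant <- contrasts$p_bonferroni < alpha
  structure(list(anova = anova_tab, contrasts = contrasts,
                 n_excluded = n_exc, alpha = alpha),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Two-way ANOVA (ratio ~ group * stage)\n")
  print(x$anova, row.names = FALSE)
  cat("\nPer-stage contrasts (Bonferroni, alpha =", x$alpha, ")\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
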