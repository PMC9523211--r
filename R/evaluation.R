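# Observer-agreement statistics: percent agreement on categorical labels,
# intraclass correlation on counts, and the paired nonparametric
# comparison (Shapiro-Wilk on differences + Wilcoxon signed-rank).

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent agreement between two label lists
#'
#' Fraction of positions where the two raters assigned the same label.
#' Symmetric and invariant under consistent relabeling.
#'
#' @param labels_a,labels_b equal-length, non-empty vectors.
#' @return agreement fraction in [0, 1].
#' @export
percent_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) == 0) stop("label lists must be non-empty")
  if (length(labels_a) != length(labels_b))
    stop("label lists must have equal length")
  mean(labels_a == labels_b)
}

icc_band <- function(icc) {
  if (icc <= 0.20) "poor"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "good"
  else "excellent"
}

#' Intraclass correlation (two-way, absolute agreement, single measure)
#'
#' Decomposes a complete subjects x raters table with a two-way ANOVA and
#' returns ICC(A,1), the absolute-agreement single-measure intraclass
#' correlation - the standard form for method comparison of counts. The
#' interpretation band uses the conventional cut-offs: <= 0.20 poor,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00
#' excellent.
#'
#' @param table numeric matrix or data.frame, subjects in rows, raters in
#'   columns; complete (no missing cells), at least 2 x 2.
#' @return list with \code{icc}, \code{band}, and the mean squares
#'   \code{msr} (rows), \code{msc} (columns), \code{mse} (residual).
#' @export
icc_agreement <- function(table) {
  m <- as.matrix(table)
  if (any(is.na(m))) stop("rating table must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (max(abs(m - m[1])) < 1e-12)              # constant table: perfect agreement
    return(list(icc = 1, band = "excellent", msr = 0, msc = 0, mse = 0))
  long <- data.frame(score = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  av <- suppressWarnings(stats::anova(stats::lm(score ~ subject + rater,
                                                data = long)))
  msr <- av["subject", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom <= 0) 1 else (msr - mse) / denom
  list(icc = icc, band = icc_band(icc), msr = msr, msc = msc, mse = mse)
}

#' Paired comparison of two count series
#'
#' Reports mean and SD of each series, a Shapiro-Wilk normality test on
#' the paired differences, and the Wilcoxon signed-rank test (zero
#' differences dropped, average ranks on ties). Degenerate inputs (all
#' differences zero, or constant differences that defeat Shapiro-Wilk) are
#' flagged rather than raising.
#'
#' @param a,b equal-length numeric vectors, length >= 5.
#' @return list with \code{mean_a}, \code{sd_a}, \code{mean_b},
#'   \code{sd_b}, \code{shapiro_w}, \code{shapiro_p}, \code{wilcoxon_v},
#'   \code{p_value}, \code{degenerate} (TRUE when every pair is tied).
#' @export
compare_counts <- function(a, b) {
  if (length(a) != length(b)) stop("count lists must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs")
  d <- a - b
  degenerate <- all(d == 0)
  sw <- tryCatch(stats::shapiro.test(d),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  wt <- if (degenerate) list(statistic = NA_real_, p.value = NA_real_) else
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                        correct = TRUE))
  list(mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       wilcoxon_v = unname(wt$statistic), p_value = wt$p.value,
       degenerate = degenerate)
}

#' Read an observer annotation table
#'
#' CSV with columns \code{clip_id}, \code{rater}, \code{wave_count},
#' \code{direction_labels} (per-wave CF/FC/CF_FC labels joined by
#' semicolons).
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_id", "rater", "wave_count")
  if (nrow(ann) == 0 || !all(need %in% names(ann)))
    stop("annotations need non-empty columns: ", paste(need, collapse = ", "))
  if (!"direction_labels" %in% names(ann)) ann$direction_labels <- ""
  ann
}

#' Agreement report across raters
#'
#' Builds, from a long annotation table, the per-rater mean (SD) wave
#' counts, the pairwise ICC matrix with interpretation bands, the pairwise
#' percent agreement of per-clip direction labels, and the pairwise
#' signed-rank comparisons.
#'
#' @param ann data.frame as returned by [read_annotations()]; every rater
#'   must cover the same clip ids.
#' @param rounding \code{"half-up"} (report fractions rounded half-up to 2
#'   decimals) or \code{"none"}.
#' @return list with \code{summary} (per rater), \code{icc} (data.frame of
#'   rater pairs), \code{direction_agreement} (data.frame of rater pairs),
#'   \code{comparisons}.
#' @export
agreement_report <- function(ann, rounding = c("half-up", "none")) {
  rounding <- match.arg(rounding)
  raters <- sort(unique(ann$rater))
  clips <- sort(unique(ann$clip_id))
  wide <- matrix(NA_real_, length(clips), length(raters),
                 dimnames = list(clips, raters))
  dirs <- matrix(NA_character_, length(clips), length(raters),
                 dimnames = list(clips, raters))
  for (i in seq_len(nrow(ann))) {
    wide[as.character(ann$clip_id[i]), as.character(ann$rater[i])] <- ann$wave_count[i]
    dirs[as.character(ann$clip_id[i]), as.character(ann$rater[i])] <- ann$direction_labels[i]
  }
  if (any(is.na(wide))) {
    miss <- clips[apply(wide, 1, anyNA)]
    stop("incomplete annotations; clips missing a rater: ",
         paste(miss, collapse = ", "))
  }
  summary <- data.frame(rater = raters,
                        mean = colMeans(wide),
                        sd = apply(wide, 2, stats::sd))
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  icc_rows <- lapply(pairs, function(p) {
    r <- icc_agreement(wide[, p])
    data.frame(rater_a = p[1], rater_b = p[2], icc = r$icc, band = r$band)
  })
  agree_rows <- lapply(pairs, function(p) {
    frac <- percent_agreement(dirs[, p[1]], dirs[, p[2]])
    data.frame(rater_a = p[1], rater_b = p[2],
               n_same = sum(dirs[, p[1]] == dirs[, p[2]]),
               agreement = if (rounding == "half-up") round_half_up(frac, 2) else frac)
  })
  comp_rows <- lapply(pairs, function(p) {
    cc <- compare_counts(wide[, p[1]], wide[, p[2]])
    data.frame(rater_a = p[1], rater_b = p[2],
               p_value = cc$p_value, degenerate = cc$degenerate)
  })
  list(summary = summary,
       icc = do.call(rbind, icc_rows),
       direction_agreement = do.call(rbind, agree_rows),
       comparisons = do.call(rbind, comp_rows))
}
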