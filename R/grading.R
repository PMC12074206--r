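## Feature ranking for House-Brackmann discrimination: Fisher score,
## Spearman correlation of the asymmetry index against the ordinal HB
## groups, and paired MOVE-vs-REST contrasts with partial eta-squared.

#' Fisher score of a feature across classes
#'
#' `FS = sum_i n_i (mu_i - mu)^2 / sum_i n_i sigma_i^2`, where `mu` is the
#' grand mean over all samples and `sigma_i^2` the within-class *population*
#' variance (divide by `n_i`; switchable to the sample convention). The
#' score is invariant under affine transforms of the values.
#'
#' @param values numeric vector of feature values.
#' @param classes class labels, same length as `values`.
#' @param variance `"population"` (default, divide by `n_i`) or `"sample"`
#'   (divide by `n_i - 1`).
#' @return The Fisher score (>= 0); `Inf` when all within-class variances
#'   vanish but class means differ.
#' @examples
#' fisherScore(c(0, 1, 2, 3), c("A", "A", "B", "B"))  # 4
#' @export
fisherScore <- function(values, classes,
                        variance = c("population", "sample")) {
  variance <- match.arg(variance)
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes[keep])
  cl <- unique(classes)
  if (length(cl) < 2L) stop("at least 2 classes are required")
  ni <- vapply(cl, function(c) sum(classes == c), numeric(1))
  if (any(ni < 2L)) stop("each class needs at least 2 samples")
  mu <- mean(values)
  mui <- vapply(cl, function(c) mean(values[classes == c]), numeric(1))
  vari <- vapply(cl, function(c) {
    x <- values[classes == c]
    if (variance == "population") mean((x - mean(x))^2)
    else stats::var(x)
  }, numeric(1))
  num <- sum(ni * (mui - mu)^2)
  den <- sum(ni * vari)
  if (den == 0) {
    if (num == 0) return(0)
    warning("all within-class variances are zero: Fisher score is infinite")
    return(Inf)
  }
  num / den
}

#' Spearman correlation of asymmetry indices with ordinal HB groups
#'
#' Rank correlation with average-rank tie handling; the two-tailed p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. For very small samples (`n <= 8`) an exact
#' permutation p-value can be requested instead.
#'
#' @param ai numeric vector of asymmetry indices.
#' @param groups ordinal group codes (numeric or [hbGroupCode()] output).
#' @param exact logical; exact permutation p (only for `n <= 8`).
#' @return List with `rho`, `p_value`, `n`.
#' @examples
#' spearmanVsHb(c(1, 2, 3, 4, 5), 0:4)
#' @export
spearmanVsHb <- function(ai, groups, exact = FALSE) {
  keep <- !is.na(ai) & !is.na(groups)
  ai <- ai[keep]; groups <- as.numeric(groups[keep])
  n <- length(ai)
  if (n < 4L) stop("at least 4 paired observations are required")
  if (length(unique(groups)) < 2L)
    stop("at least 2 distinct group codes are required")
  if (stats::sd(ai) == 0) {
    warning("constant asymmetry values: Spearman rho is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  r1 <- rank(ai); r2 <- rank(groups)
  rho <- stats::cor(r1, r2)
  if (exact) {
    if (n > 8L)
      stop("exact permutation p-value supported only for n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(r1[p], r2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Paired MOVE-versus-REST contrast
#'
#' Two-level within-subject contrast of one feature: paired t statistic on
#' per-subject (MOVE - REST) means, `df = n - 1`, two-tailed p, and the
#' effect size `partial_eta_sq = t^2 / (t^2 + df)`.
#'
#' @param move_means,rest_means per-subject feature means under MOVE and
#'   REST (paired, same order, `n >= 3`).
#' @return List: `mean_move`, `mean_rest`, `t_stat`, `df`, `p_value`,
#'   `partial_eta_sq`, `degenerate`. Zero-variance differences are flagged
#'   degenerate: all-zero differences give `t = 0`, `p = 1`,
#'   `partial_eta_sq = 0`; a constant non-zero shift gives `NA` statistics.
#' @examples
#' motionContrast(c(5, 6, 7, 8), c(1, 1.5, 2, 2.2))
#' @export
motionContrast <- function(move_means, rest_means) {
  if (length(move_means) != length(rest_means))
    stop("move and rest vectors must be paired (equal length)")
  keep <- !is.na(move_means) & !is.na(rest_means)
  mv <- move_means[keep]; rs <- rest_means[keep]
  n <- length(mv)
  if (n < 3L) stop("at least 3 paired subjects are required")
  d <- mv - rs
  df <- n - 1L
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(mean_move = mean(mv), mean_rest = mean(rs), t_stat = 0,
                  df = df, p_value = 1, partial_eta_sq = 0,
                  degenerate = TRUE))
    warning("zero-variance non-zero differences: paired t undefined")
    return(list(mean_move = mean(mv), mean_rest = mean(rs),
                t_stat = NA_real_, df = df, p_value = NA_real_,
                partial_eta_sq = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(mv, rs, paired = TRUE)
  tstat <- unname(tt$statistic)
  list(mean_move = mean(mv), mean_rest = mean(rs), t_stat = tstat,
       df = unname(tt$parameter), p_value = tt$p.value,
       partial_eta_sq = tstat^2 / (tstat^2 + unname(tt$parameter)),
       degenerate = FALSE)
}

#' Feature ranking table: Fisher score and Spearman rho per feature
#'
#' For each (movement, intensity, feature) cell of an asymmetry table,
#' computes the Fisher score of the AI across HB groups and the Spearman
#' correlation of the AI with the ordinal group code.
#'
#' @param ai_table output of [buildAsymmetryTable()].
#' @param condition which intervals' AI to rank on (default `"MOVE"`).
#' @param adjust_p logical; add a Benjamini-Hochberg adjusted p column
#'   (`p_adj`, adjusted within each movement run). Default FALSE: raw
#'   two-tailed p-values, clearly labelled `spearman_p`.
#' @param variance Fisher-score variance convention, see [fisherScore()].
#' @return data.frame: `movement`, `intensity`, `feature`, `fisher_score`,
#'   `spearman_rho`, `spearman_p`, `n` (+ `p_adj` when requested).
#' @export
featureRankingTable <- function(ai_table, condition = "MOVE",
                                adjust_p = FALSE,
                                variance = "population") {
  sub <- ai_table[ai_table$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for condition ", condition)
  groups <- split(sub, sub[c("movement", "intensity", "feature")],
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    ok <- !is.na(g$ai_percent)
    fs <- if (sum(ok) >= 4L &&
              length(unique(g$hb_group[ok])) >= 2L)
      fisherScore(g$ai_percent[ok], g$hb_group[ok], variance = variance)
    else NA_real_
    sp <- if (sum(ok) >= 4L && length(unique(g$hb_group[ok])) >= 2L &&
              stats::sd(g$ai_percent[ok]) > 0)
      spearmanVsHb(g$ai_percent[ok], g$hb_group[ok])
    else list(rho = NA_real_, p_value = NA_real_)
    data.frame(movement = g$movement[1L], intensity = g$intensity[1L],
               feature = g$feature[1L], fisher_score = fs,
               spearman_rho = sp$rho, spearman_p = sp$p_value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$movement, out$intensity, out$feature), ]
  if (adjust_p) {
    out$p_adj <- stats::ave(out$spearman_p,
                            paste(out$movement, out$intensity),
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  rownames(out) <- NULL
  out
}

#' MOVE-versus-REST contrast table
#'
#' Runs [motionContrast()] for every (feature, movement, intensity, side)
#' cell of a per-subject aggregated feature table.
#'
#' @param subject_features long data.frame of trial-aggregated means
#'   (columns `subject_id`, `movement`, `intensity`, `side`, `condition`,
#'   `feature`, `mean`).
#' @param metadata optional data.frame with `subject_id` plus grouping
#'   columns; when given with `by_group = TRUE`, contrasts are additionally
#'   computed per HB group.
#' @param by_group logical, see above.
#' @return data.frame with one row per cell: means, t, df, p, partial
#'   eta-squared and the degenerate flag (and `hb_group` when grouped).
#' @export
motionContrastTable <- function(subject_features, metadata = NULL,
                                by_group = FALSE) {
  sf <- subject_features
  if (by_group) {
    if (is.null(metadata)) stop("metadata required when by_group = TRUE")
    m <- match(sf$subject_id, metadata$subject_id)
    sf$hb_group <- hbGroupCode(metadata$hb_grade[m], metadata$is_control[m])
  }
  keys <- c("movement", "intensity", "side", "feature",
            if (by_group) "hb_group")
  groups <- split(sf, sf[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    wide <- data.table::dcast(data.table::as.data.table(g),
                              subject_id ~ condition, value.var = "mean")
    if (!all(c("MOVE", "REST") %in% names(wide)) || nrow(wide) < 3L)
      return(NULL)
    ct <- motionContrast(wide$MOVE, wide$REST)
    data.frame(g[1L, keys, drop = FALSE],
               n = nrow(wide),
               mean_move = ct$mean_move, mean_rest = ct$mean_rest,
               t_stat = ct$t_stat, df = ct$df, p_value = ct$p_value,
               partial_eta_sq = ct$partial_eta_sq,
               degenerate = ct$degenerate,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("no complete MOVE/REST cells with >= 3 subjects")
  rownames(out) <- NULL
  out
}

#' Order features by descending Fisher score
#'
#' @param ranking a [featureRankingTable()] result (one or more movements).
#' @param movement,intensity optional filters selecting one movement run.
#' @param threshold Fisher-score highlight threshold (default 0.2).
#' @return The selected rows sorted by descending `fisher_score` (ties
#'   broken lexicographically by feature name), with a logical `flagged`
#'   column marking scores `>= threshold`.
#' @export
rankFeatures <- function(ranking, movement = NULL, intensity = NULL,
                         threshold = 0.2) {
  out <- ranking
  if (!is.null(movement)) out <- out[out$movement == movement, ]
  if (!is.null(intensity)) out <- out[out$intensity == intensity, ]
  if (nrow(out) == 0L) stop("empty ranking table after filtering")
  out <- out[order(-out$fisher_score, out$feature), ]
  out$flagged <- !is.na(out$fisher_score) & out$fisher_score >= threshold
  rownames(out) <- NULL
  out
}
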