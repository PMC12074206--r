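## Bilateral asymmetry index (AI).
##
## AI = (healthy - lesioned) / (healthy + lesioned) * 100, in percent:
## 0% is complete symmetry, +100% complete absence of lesioned-side
## activity. The index is signed (a lesioned side stronger than the healthy
## side is informative) and scale-invariant, which is what makes it
## comparable across subjects despite large absolute-amplitude variability.

#' Asymmetry index between healthy- and lesioned-side feature values
#'
#' @param healthy,lesioned numeric vectors of same-feature, same-condition
#'   values (recycled to a common length).
#' @param magnitude logical; if TRUE, absolute values are taken first, the
#'   documented mode for sign-crossing features such as skewness. If FALSE
#'   (default) negative inputs are refused with an error.
#' @return `(healthy - lesioned) / (healthy + lesioned) * 100`. A zero
#'   denominator yields NaN with a warning.
#' @examples
#' asymmetryIndex(5, 5)        # 0: complete symmetry
#' asymmetryIndex(1, 0)        # 100: one-sided absence
#' asymmetryIndex(0.5, 1.5)    # -50
#' @export
asymmetryIndex <- function(healthy, lesioned, magnitude = FALSE) {
  if (magnitude) {
    healthy <- abs(healthy); lesioned <- abs(lesioned)
  } else if (any(healthy < 0, na.rm = TRUE) ||
             any(lesioned < 0, na.rm = TRUE)) {
    stop("negative feature values: the asymmetry index is undefined for ",
         "sign-crossing features; use magnitude = TRUE")
  }
  denom <- healthy + lesioned
  out <- (healthy - lesioned) / denom * 100
  zero <- !is.na(denom) & denom == 0
  if (any(zero)) {
    warning("zero denominator: asymmetry index undefined, returning NaN")
    out[zero] <- NaN
  }
  out
}

#' Build the per-subject asymmetry table
#'
#' Pairs the two facial sides of each subject's trial-aggregated feature
#' means and computes the asymmetry index per (subject, movement, intensity,
#' condition, feature). For healthy controls, who have no lesioned side, a
#' pseudo-lesioned side is assigned by convention (default left) so controls
#' contribute near-zero AI values.
#'
#' Sign-crossing features (skewness) get `NA` AI with a warning unless
#' `magnitude = TRUE`, which computes the index on absolute values — the
#' mode used for feature-ranking analyses.
#'
#' @param subject_features long data.frame of trial-aggregated means with
#'   columns `subject_id`, `movement`, `intensity`, `side`, `condition`,
#'   `feature`, `mean` (as produced by [aggregateTrials()] plus a
#'   `subject_id` column).
#' @param metadata data.frame with `subject_id`, `hb_grade`, `is_control`,
#'   `lesioned_side` (`"left"`, `"right"` or `"none"`).
#' @param control_lesioned side treated as "lesioned" for controls
#'   (default `"left"`).
#' @param magnitude logical, see above.
#' @return data.frame: `subject_id`, `movement`, `intensity`, `condition`,
#'   `feature`, `healthy`, `lesioned`, `ai_percent`, `hb_grade`, `hb_group`.
#' @export
buildAsymmetryTable <- function(subject_features, metadata,
                                control_lesioned = "left",
                                magnitude = FALSE) {
  need <- c("subject_id", "movement", "intensity", "side", "condition",
            "feature", "mean")
  miss <- setdiff(need, names(subject_features))
  if (length(miss))
    stop("subject_features is missing columns: ", paste(miss, collapse = ", "))
  stopifnot(control_lesioned %in% .SIDES)

  md <- metadata
  md$lesioned_eff <- ifelse(md$lesioned_side == "none",
                            control_lesioned, md$lesioned_side)
  md$hb_group <- hbGroupCode(md$hb_grade, md$is_control)

  dt <- data.table::as.data.table(subject_features)
  wide <- data.table::dcast(
    dt, subject_id + movement + intensity + condition + feature ~ side,
    value.var = "mean")
  for (s in .SIDES) if (!s %in% names(wide))
    stop("both facial sides are required; missing side: ", s)
  if (anyNA(wide$left) || anyNA(wide$right)) {
    bad <- wide[is.na(wide$left) | is.na(wide$right)]
    stop("missing side values for: ",
         paste(utils::head(paste(bad$subject_id, bad$movement,
                                 bad$condition, bad$feature), 5),
               collapse = "; "))
  }
  data.table::setDF(wide)

  m <- match(wide$subject_id, md$subject_id)
  if (anyNA(m)) stop("subjects absent from metadata: ",
                     paste(unique(wide$subject_id[is.na(m)]), collapse = ", "))
  les_side <- md$lesioned_eff[m]
  wide$lesioned <- ifelse(les_side == "left", wide$left, wide$right)
  wide$healthy <- ifelse(les_side == "left", wide$right, wide$left)
  wide$hb_grade <- md$hb_grade[m]
  wide$hb_group <- md$hb_group[m]

  wide$ai_percent <- NA_real_
  signed <- !(wide$feature %in% .SIGNED_FEATURES)
  neg <- signed & (wide$healthy < 0 | wide$lesioned < 0)
  if (any(neg, na.rm = TRUE))
    stop("negative values in nominally non-negative features: ",
         paste(unique(wide$feature[neg]), collapse = ", "))
  if (magnitude) {
    wide$ai_percent <- asymmetryIndex(wide$healthy, wide$lesioned,
                                      magnitude = TRUE)
  } else {
    wide$ai_percent[signed] <- asymmetryIndex(wide$healthy[signed],
                                              wide$lesioned[signed])
    if (any(!signed))
      warning("AI left NA for sign-crossing feature(s): ",
              paste(unique(wide$feature[!signed]), collapse = ", "),
              " (use magnitude = TRUE)")
  }
  cols <- c("subject_id", "movement", "intensity", "condition", "feature",
            "healthy", "lesioned", "ai_percent", "hb_grade", "hb_group")
  out <- wide[order(wide$subject_id, wide$movement, wide$intensity,
                    wide$condition, wide$feature), cols]
  rownames(out) <- NULL
  out
}
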