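# Relative expression by 2^-ddCt, anthocyanin units and one-way
# ANOVA + Tukey HSD compact letter display.

#' Relative expression by the 2^-ddCt method
#'
#' Replicates are averaged on the Ct scale first; dCt = mean target Ct -
#' mean reference Ct per (gene, sample); ddCt = dCt(sample) -
#' dCt(calibrator); fold = 2^-ddCt. The calibrator fold is exactly 1.
#'
#' @param records Tibble with gene_id, sample_id, replicate, ct_target,
#'   ct_reference.
#' @param calibrator Calibrator sample id (default "DAF1", the un-stressed
#'   control convention).
#' @param per_replicate Also return per-replicate folds with mean and
#'   standard error (for error bars).
#' @return Wide tibble gene_id x sample fold changes; with
#'   `per_replicate`, a list of the wide table plus a long per-replicate
#'   table with mean +- SE.
#' @export
delta_delta_ct <- function(records, calibrator = "DAF1",
                           per_replicate = FALSE) {
  stopifnot(all(c("gene_id", "sample_id", "replicate", "ct_target",
                  "ct_reference") %in% names(records)))
  stopifnot(all(records$ct_target > 0 & records$ct_target < 45),
            all(records$ct_reference > 0 & records$ct_reference < 45))
  have_cal <- tapply(records$sample_id == calibrator, records$gene_id, any)
  if (!all(have_cal)) {
    stop("missing calibrator sample for gene(s): ",
         paste(names(have_cal)[!have_cal], collapse = ", "))
  }
  dct <- dplyr::summarise(
    dplyr::group_by(records, .data$gene_id, .data$sample_id),
    dct = mean(.data$ct_target) - mean(.data$ct_reference),
    .groups = "drop")
  cal <- dct[dct$sample_id == calibrator, c("gene_id", "dct")]
  names(cal)[2] <- "dct_cal"
  dct <- dplyr::left_join(dct, cal, by = "gene_id")
  dct$fold <- 2^(-(dct$dct - dct$dct_cal))
  dct$fold[dct$sample_id == calibrator] <- 1
  sample_order <- unique(records$sample_id)
  dct$sample_id <- factor(dct$sample_id, levels = sample_order)
  dct <- dct[order(dct$gene_id, dct$sample_id), ]
  dct$sample_id <- as.character(dct$sample_id)
  wide <- tidyr::pivot_wider(dct[, c("gene_id", "sample_id", "fold")],
                             names_from = "sample_id", values_from = "fold")
  if (!per_replicate) return(wide)
  rep_dct <- dplyr::mutate(records,
                           dct = .data$ct_target - .data$ct_reference)
  rep_dct <- dplyr::left_join(rep_dct, cal, by = "gene_id")
  rep_dct$fold <- 2^(-(rep_dct$dct - rep_dct$dct_cal))
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(rep_dct, .data$gene_id, .data$sample_id),
    mean_fold = mean(.data$fold),
    se_fold = stats::sd(.data$fold) / sqrt(dplyr::n()),
    .groups = "drop")
  list(fold = wide, replicates = rep_dct, summary = stats_tbl)
}

#' Anthocyanin units per gram fresh weight
#'
#' U = (OD530 - OD600) / gFW. Negative values (blank-subtraction
#' artifacts) are allowed but flagged.
#'
#' @param od530,od600 Absorbances (>= 0).
#' @param mass Fresh weight in grams (> 0).
#' @return Tibble with columns units and flag_negative.
#' @export
anthocyanin_units <- function(od530, od600, mass) {
  if (any(mass <= 0)) stop("mass must be positive")
  stopifnot(all(od530 >= 0), all(od600 >= 0))
  u <- (od530 - od600) / mass
  tibble::tibble(units = u, flag_negative = u < 0)
}

#' One-way ANOVA with Tukey HSD compact letters
#'
#' One-way ANOVA (F = MS_between / MS_within) followed by Tukey honestly
#' significant difference pairwise comparisons (Tukey-Kramer for
#' unbalanced designs) and a compact letter display assigned greedily from
#' the largest mean; groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, >= 2 replicates each).
#' @param alpha Significance level (default 0.05).
#' @return List with `F`, `p_value`, `tukey` (pairwise table) and
#'   `letters` (tibble: group, mean, letters).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L))
  ss_within <- sum(unlist(tapply(values, groups,
                                 function(v) (v - mean(v))^2)))
  if (ss_within == 0) {
    stop("zero within-group variance; ANOVA is undefined")
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  gnames <- names(means)
  padj <- function(g1, g2) {
    key1 <- paste0(g1, "-", g2); key2 <- paste0(g2, "-", g1)
    if (key1 %in% rownames(tk)) tk[key1, "p adj"] else tk[key2, "p adj"]
  }
  differ <- function(g1, g2) padj(g1, g2) < alpha
  letter_groups <- list(gnames[1])
  for (g in gnames[-1]) {
    placed <- FALSE
    for (li in seq_along(letter_groups)) {
      if (!any(vapply(letter_groups[[li]], differ, logical(1), g2 = g))) {
        letter_groups[[li]] <- c(letter_groups[[li]], g)
        placed <- TRUE
      }
    }
    if (!placed) letter_groups[[length(letter_groups) + 1L]] <- g
  }
  # absorb letter sets fully contained in another
  keep <- rep(TRUE, length(letter_groups))
  for (i in seq_along(letter_groups)) {
    for (j in seq_along(letter_groups)) {
      if (i != j && keep[j] &&
          all(letter_groups[[i]] %in% letter_groups[[j]]) &&
          (length(letter_groups[[i]]) < length(letter_groups[[j]]) ||
           (length(letter_groups[[i]]) == length(letter_groups[[j]]) && i > j))) {
        keep[i] <- FALSE
      }
    }
  }
  letter_groups <- letter_groups[keep]
  labels <- vapply(gnames, function(g) {
    paste(letters[which(vapply(letter_groups, function(s) g %in% s,
                               logical(1)))], collapse = "")
  }, character(1))
  list(
    F = an[1, "F value"],
    p_value = an[1, "Pr(>F)"],
    tukey = tk,
    letters = tibble::tibble(group = gnames, mean = as.numeric(means),
                             letters = unname(labels))
  )
}
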