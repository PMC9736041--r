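#' Per-patient relative difference between two modalities
#'
#' \code{(a - b) / b x 100}, the percent change of modality A relative to the
#' comparator modality B (the second-named modality of a contrast, e.g.
#' protons in "He vs H+"). A zero comparator yields NA rather than an error;
#' such patients are handled by the exclusion accounting.
#'
#' @param a numeric, values under modality A.
#' @param b numeric, values under the comparator modality B.
#' @return Numeric vector of percent differences.
#' @examples
#' relativeDifference(15, 20)  # -25
#' @export
relativeDifference <- function(a, b) {
  out <- (a - b) / b * 100
  out[b == 0] <- NA_real_
  out
}

#' Low-dose exclusion rules for paired metric values
#'
#' A patient's value for a metric is excluded from relative-difference and
#' statistical analysis when the value is below \code{threshold} (1 Gy) for
#' all modalities simultaneously; when more than \code{maxExcluded} (five)
#' patients are excluded the whole row is marked not applicable and carries
#' no relative differences. The rules are idempotent and order-independent:
#' they depend only on the value matrix.
#'
#' @param values numeric matrix, patients in rows, modalities in columns.
#' @param threshold exclusion threshold in Gy (default 1).
#' @param maxExcluded maximum tolerated exclusions before the row becomes
#'   not applicable (default 5).
#' @return List with \code{include} (logical per patient), \code{nExcluded},
#'   and \code{notApplicable}.
#' @examples
#' applyExclusionRules(rbind(c(0.5, 0.8, 0.9), c(0.5, 1.2, 2.0)))
#' @export
applyExclusionRules <- function(values, threshold = 1, maxExcluded = 5) {
  values <- as.matrix(values)
  include <- !apply(values < threshold, 1L, all)
  include[apply(is.na(values), 1L, any)] <- FALSE
  n_ex <- sum(!include)
  list(include = include, nExcluded = n_ex,
       notApplicable = n_ex > maxExcluded)
}

.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(if (length(x)) 0 else NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# long df -> per-patient wide matrix for one (structure, metric)
.wideValues <- function(df, valueCol) {
  pats <- sort(unique(df$patient_id))
  out <- matrix(NA_real_, length(pats), length(.MODALITIES),
                dimnames = list(pats, .MODALITIES))
  for (m in .MODALITIES) {
    sub <- df[df$modality == m, ]
    out[sub$patient_id, m] <- sub[[valueCol]]
  }
  out
}

#' Paired three-modality comparison summary
#'
#' Reproduces the plan-comparison table layout for a long-format record set:
#' per (structure, metric) row, modality means with standard errors of the
#' mean, per-patient contrasts helium vs protons and protons vs photons
#' (relative percent differences for dosimetric records, absolute
#' differences for NTCP records), the Friedman test across the three
#' modalities and the two-sided Wilcoxon signed-rank post-test per contrast
#' with significance flagged at p < 0.05. The low-dose exclusion rules are
#' applied before any statistics for Gy-scaled metrics; a row excluded for
#' more than five patients carries NA contrasts (rendered as "nan"). NTCP
#' records (\code{type = "ntcp"}) are summarised on the percent scale.
#'
#' @param records data.frame with columns \code{patient_id},
#'   \code{modality}, \code{structure}, \code{value} and either
#'   \code{metric} (dosimetric) or \code{endpoint} (NTCP; the \code{ntcp}
#'   column is used as value).
#' @param type \code{"dosimetric"} or \code{"ntcp"}.
#' @param threshold exclusion threshold in Gy.
#' @param maxExcluded row-level exclusion cap.
#' @return data.frame, one row per (structure, metric), with columns
#'   \code{mean_*}/\code{sem_*} per modality, contrast columns
#'   \code{diff_he_pr}, \code{sem_he_pr}, \code{p_he_pr}, \code{sig_he_pr}
#'   (and \code{*_pr_ph}), \code{friedman_chisq}, \code{friedman_p},
#'   \code{n}, \code{n_excluded}, \code{not_applicable} and
#'   \code{diff_type}.
#' @seealso [renderComparisonTable()]
#' @export
summarizeComparison <- function(records, type = c("dosimetric", "ntcp"),
                                threshold = 1, maxExcluded = 5) {
  type <- match.arg(type)
  if (type == "ntcp") {
    records <- data.frame(
      patient_id = records$patient_id, modality = records$modality,
      structure = records$structure, metric = records$endpoint,
      value = records$ntcp * 100, unit = "percent_prob",
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("patient_id", "modality", "structure", "metric",
                  "value") %in% names(records)))
  keys <- unique(records[, c("structure", "metric")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- records[records$structure == keys$structure[i] &
                     records$metric == keys$metric[i], ]
    wide <- .wideValues(sub, "value")
    unit <- if (type == "ntcp") "percent_prob" else
      metricUnits(keys$metric[i])
    gyScaled <- unit %in% c("Gy", "Gy_cm3")
    excl <- if (gyScaled)
      applyExclusionRules(wide, threshold, maxExcluded)
    else
      list(include = stats::complete.cases(wide), nExcluded = 0L,
           notApplicable = FALSE)
    keep <- wide[excl$include, , drop = FALSE]
    na_row <- excl$notApplicable || nrow(keep) < 2L

    if (!na_row) {
      d_he_pr <- if (type == "ntcp")
        keep[, "helium"] - keep[, "proton"]
      else relativeDifference(keep[, "helium"], keep[, "proton"])
      d_pr_ph <- if (type == "ntcp")
        keep[, "proton"] - keep[, "photon"]
      else relativeDifference(keep[, "proton"], keep[, "photon"])
      fr <- friedmanTest(keep)
      w_he_pr <- wilcoxonSignedRank(keep[, "helium"], keep[, "proton"])
      w_pr_ph <- wilcoxonSignedRank(keep[, "proton"], keep[, "photon"])
    } else {
      d_he_pr <- d_pr_ph <- NA_real_
      fr <- list(statistic = NA_real_, p.value = NA_real_)
      w_he_pr <- w_pr_ph <- list(p.value = NA_real_)
    }
    rows[[i]] <- data.frame(
      structure = keys$structure[i], metric = keys$metric[i], unit = unit,
      n = nrow(keep), n_excluded = excl$nExcluded,
      not_applicable = na_row,
      mean_helium = mean(wide[, "helium"], na.rm = TRUE),
      sem_helium = .sem(wide[, "helium"]),
      mean_proton = mean(wide[, "proton"], na.rm = TRUE),
      sem_proton = .sem(wide[, "proton"]),
      mean_photon = mean(wide[, "photon"], na.rm = TRUE),
      sem_photon = .sem(wide[, "photon"]),
      diff_he_pr = if (na_row) NA_real_ else mean(d_he_pr, na.rm = TRUE),
      sem_he_pr = if (na_row) NA_real_ else .sem(d_he_pr),
      p_he_pr = w_he_pr$p.value,
      sig_he_pr = !na_row && !is.na(w_he_pr$p.value) &&
        w_he_pr$p.value < 0.05,
      diff_pr_ph = if (na_row) NA_real_ else mean(d_pr_ph, na.rm = TRUE),
      sem_pr_ph = if (na_row) NA_real_ else .sem(d_pr_ph),
      p_pr_ph = w_pr_ph$p.value,
      sig_pr_ph = !na_row && !is.na(w_pr_ph$p.value) &&
        w_pr_ph$p.value < 0.05,
      friedman_chisq = fr$statistic, friedman_p = fr$p.value,
      diff_type = if (type == "ntcp") "absolute_pct" else "relative_pct",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
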