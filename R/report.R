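#' Render a comparison summary as a human-readable table
#'
#' Formats each cell as \code{value +/- sem} with the SEM rounded to two
#' significant figures and the value rounded to the SEM's last decimal
#' (machine-precision values stay in the summary data.frame; rendering only
#' affects the human table). Significant contrasts (Wilcoxon p < 0.05) carry
#' a trailing \code{" *"}; not-applicable cells render as \code{"nan +/- nan"}.
#'
#' @param rows output of [summarizeComparison()].
#' @return data.frame of characters with columns structure, metric, one per
#'   modality and one per contrast.
#' @export
renderComparisonTable <- function(rows) {
  if (nrow(rows) == 0L)
    return(data.frame(structure = character(), metric = character(),
                      helium = character(), proton = character(),
                      photon = character(), he_vs_pr = character(),
                      pr_vs_ph = character(), stringsAsFactors = FALSE))
  fmt <- function(v, s, sig = FALSE, na = FALSE) {
    if (na || is.na(v)) return("nan ± nan")
    if (is.na(s) || s == 0) {
      cell <- sprintf("%g ± 0", signif(v, 6))
    } else {
      s2 <- signif(s, 2)
      dec <- max(0, -floor(log10(s2)) + 1)
      dec <- min(dec, 6)
      cell <- sprintf("%.*f ± %.*f", dec, round(v, dec), dec, s2)
    }
    if (sig) paste0(cell, " *") else cell
  }
  data.frame(
    structure = rows$structure, metric = rows$metric,
    helium = mapply(fmt, rows$mean_helium, rows$sem_helium),
    proton = mapply(fmt, rows$mean_proton, rows$sem_proton),
    photon = mapply(fmt, rows$mean_photon, rows$sem_photon),
    he_vs_pr = mapply(fmt, rows$diff_he_pr, rows$sem_he_pr,
                      rows$sig_he_pr, rows$not_applicable),
    pr_vs_ph = mapply(fmt, rows$diff_pr_ph, rows$sem_pr_ph,
                      rows$sig_pr_ph, rows$not_applicable),
    stringsAsFactors = FALSE)
}

#' Cohort-mean cumulative DVH overlay
#'
#' Per structure, the cumulative DVH averaged over patients, one curve per
#' modality, faceted by structure.
#'
#' @param cohort named list of [PlanSet-class] (e.g. from
#'   [generateCohort()] or [readDVHDir()]).
#' @return A ggplot object.
#' @export
plotDVHOverlay <- function(cohort) {
  dfs <- lapply(cohort, function(plan) {
    do.call(rbind, lapply(plan@curves, function(cv) {
      cum <- if (cv@kind == "cumulative") cv else
        differentialToCumulative(cv)
      data.frame(modality = plan@modality, structure = cv@structure,
                 dose = cum@doseEdges, volume = cum@relVolume,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, dfs)
  agg <- stats::aggregate(volume ~ modality + structure + dose, df, mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$dose, y = 100 * .data$volume,
                                    colour = .data$modality)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~structure, scales = "free_x") +
    ggplot2::labs(x = "Dose [Gy]", y = "Volume [%]",
                  title = "Cohort-mean cumulative DVH") +
    ggplot2::theme_bw()
}

#' NTCP distribution boxplots with a helium-minus-proton panel
#'
#' Boxplots of per-patient NTCP (percent) per modality, faceted by
#' (structure, endpoint), plus a panel of the per-patient paired difference
#' NTCP(helium) - NTCP(protons).
#'
#' @param ntcpRecords data.frame from [ntcpBattery()] rows bound together.
#' @return A ggplot object.
#' @export
plotNTCPBoxplots <- function(ntcpRecords) {
  df <- ntcpRecords
  df$panel <- paste(df$structure, df$endpoint, sep = "\n")
  df$value <- df$ntcp * 100
  delta <- deltaNTCP(ntcpRecords)
  delta$panel <- paste(delta$structure, delta$endpoint, sep = "\n")
  delta$modality <- "Δ He-H+"
  delta$value <- delta$delta_ntcp * 100
  keep <- c("panel", "modality", "value")
  all <- rbind(df[, keep], delta[, keep])
  all$modality <- factor(all$modality,
                         levels = c("helium", "proton", "photon",
                                    "Δ He-H+"))
  ggplot2::ggplot(all, ggplot2::aes(x = .data$modality, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "NTCP [%]",
                  title = "NTCP per modality and paired helium-proton difference") +
    ggplot2::theme_bw()
}

#' Per-patient paired NTCP difference helium minus protons
#'
#' @param ntcpRecords data.frame with patient_id, modality, structure,
#'   endpoint, ntcp.
#' @return data.frame with one row per (patient, structure, endpoint) and a
#'   \code{delta_ntcp} column (probability scale).
#' @export
deltaNTCP <- function(ntcpRecords) {
  he <- ntcpRecords[ntcpRecords$modality == "helium", ]
  pr <- ntcpRecords[ntcpRecords$modality == "proton", ]
  m <- merge(he, pr, by = c("patient_id", "structure", "endpoint"),
             suffixes = c("_he", "_pr"))
  data.frame(patient_id = m$patient_id, structure = m$structure,
             endpoint = m$endpoint,
             delta_ntcp = m$ntcp_he - m$ntcp_pr, stringsAsFactors = FALSE)
}

#' Run the full plan-comparison pipeline
#'
#' End-to-end orchestration: obtain plans (generate a synthetic cohort from
#' a [CohortConfig-class], or read \code{.dvh} files from a directory),
#' compute the dosimetric metric battery and the NTCP battery, summarise the
#' paired three-modality comparison, and write all outputs to
#' \code{outDir}: \code{dvh/*.dvh} (when generating), \code{metrics.csv},
#' \code{ntcp.csv}, \code{delta_ntcp.csv},
#' \code{comparison_dosimetric.csv}, \code{comparison_ntcp.csv}, rendered
#' tables \code{tables/table_dosimetric.csv} and
#' \code{tables/table_ntcp.csv}, figures \code{dvh_overlay.png} and
#' \code{ntcp_boxplots.png} (skipped with a message if no PNG device is
#' available), and \code{manifest.json} recording configuration, seed,
#' exclusion tallies and package version. All outputs are a pure function
#' of the input: re-running with the same configuration reproduces them
#' byte-identically (CSV/JSON).
#'
#' @param input a [CohortConfig-class] or a directory of \code{.dvh} files.
#' @param outDir output directory (created if needed).
#' @param params LKB registry, see [defaultLKBParameters()].
#' @param structureMap see [defaultStructureMap()].
#' @param writePlots logical, render PNG figures.
#' @param writeDVH logical, write generated plans as .dvh files.
#' @return Invisibly, a list with the cohort, metric and NTCP records, both
#'   comparison summaries and the manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(cohortConfig(nPatients = 3, seed = 1),
#'                    outDir = tempfile(), writePlots = FALSE)
#' }
#' @export
runPipeline <- function(input, outDir, params = defaultLKBParameters(),
                        structureMap = defaultStructureMap(),
                        writePlots = TRUE, writeDVH = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    if (is(input, "CohortConfig")) {
      cohort <- generateCohort(input)
      if (writeDVH) {
        dvhDir <- file.path(outDir, "dvh")
        dir.create(dvhDir, showWarnings = FALSE)
        for (nm in names(cohort))
          writeDVHFile(cohort[[nm]], file.path(dvhDir,
                                               paste0(nm, ".dvh")))
      }
      seed <- input@seed
    } else if (is.character(input) && dir.exists(input)) {
      cohort <- readDVHDir(input)
      seed <- NA
    } else {
      .errBadArgument("input must be a CohortConfig or a directory path")
    }

    stage <- "metrics"
    metrics <- do.call(rbind, lapply(cohort, metricBattery))
    rownames(metrics) <- NULL
    utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)

    stage <- "ntcp"
    ntcp <- do.call(rbind, lapply(cohort, ntcpBattery, params = params,
                                  structureMap = structureMap))
    rownames(ntcp) <- NULL
    utils::write.csv(ntcp, file.path(outDir, "ntcp.csv"), row.names = FALSE)
    dn <- deltaNTCP(ntcp)
    utils::write.csv(dn, file.path(outDir, "delta_ntcp.csv"),
                     row.names = FALSE)

    stage <- "comparison"
    cmpDose <- summarizeComparison(metrics, type = "dosimetric")
    cmpNtcp <- summarizeComparison(ntcp, type = "ntcp")
    utils::write.csv(cmpDose, file.path(outDir, "comparison_dosimetric.csv"),
                     row.names = FALSE)
    utils::write.csv(cmpNtcp, file.path(outDir, "comparison_ntcp.csv"),
                     row.names = FALSE)
    tabDir <- file.path(outDir, "tables")
    dir.create(tabDir, showWarnings = FALSE)
    utils::write.csv(renderComparisonTable(cmpDose),
                     file.path(tabDir, "table_dosimetric.csv"),
                     row.names = FALSE)
    utils::write.csv(renderComparisonTable(cmpNtcp),
                     file.path(tabDir, "table_ntcp.csv"), row.names = FALSE)

    stage <- "figures"
    if (writePlots) {
      ok <- tryCatch({
        ggplot2::ggsave(file.path(outDir, "dvh_overlay.png"),
                        plotDVHOverlay(cohort), width = 10, height = 8,
                        dpi = 120)
        ggplot2::ggsave(file.path(outDir, "ntcp_boxplots.png"),
                        plotNTCPBoxplots(ntcp), width = 9, height = 6,
                        dpi = 120)
        TRUE
      }, error = function(e) {
        message("figure rendering skipped: ", conditionMessage(e))
        FALSE
      })
    } else ok <- FALSE

    stage <- "manifest"
    manifest <- list(
      package = "ionNTCP",
      version = as.character(utils::packageVersion("ionNTCP")),
      seed = seed,
      n_plans = length(cohort),
      patients = sort(unique(vapply(cohort, patientID, character(1)))),
      structures = sort(unique(metrics$structure)),
      excluded_patients_by_row = stats::setNames(
        as.list(cmpDose$n_excluded),
        paste(cmpDose$structure, cmpDose$metric, sep = ".")),
      figures_rendered = ok,
      outputs = sort(list.files(outDir, recursive = TRUE)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(cohort = cohort, metrics = metrics, ntcp = ntcp,
         delta_ntcp = dn, comparison_dosimetric = cmpDose,
         comparison_ntcp = cmpNtcp, manifest = manifest)
  }, dvhError = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
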