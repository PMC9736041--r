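#' Read and write plain-text DVH files
#'
#' One file holds all structures of one (patient, modality) plan in a
#' self-contained UTF-8 dialect:
#' \preformatted{
#' # patient: P01
#' # modality: proton
#' # prescription_Gy: 54.000000
#' # fractions: 30
#' # dose_per_fraction_Gy: 1.800000
#' ## structure: ctv
#' ## volume_cm3: 60.000000
#' ## kind: cumulative
#' 0.000000,1.000000
#' ...
#' }
#' Doses and volumes are written with six decimal places, which fixes the
#' representable resolution of the format (1e-6 Gy / 1e-6 relative volume);
#' reading a written file reproduces the plan at that precision and a second
#' write is byte-identical. Parse and validation failures are raised as
#' classed conditions (\code{dvhMalformedHeader}, \code{dvhMissingMetadata},
#' \code{dvhNonMonotone}, \code{dvhNegativeVolume}) so callers can
#' distinguish them.
#'
#' @param path file path.
#' @param plan a valid [PlanSet-class].
#' @return \code{readDVHFile}: a validated [PlanSet-class].
#'   \code{writeDVHFile}: the path, invisibly.
#' @examples
#' p <- planSet(list(dvhCurve(c(0, 10, 20), c(1, 0.4, 0), structure = "ctv",
#'                            patientID = "P01")),
#'              patientID = "P01", prescriptionDose = 54)
#' f <- tempfile(fileext = ".dvh")
#' writeDVHFile(p, f)
#' readDVHFile(f)
#' @export
readDVHFile <- function(path) {
  if (!file.exists(path))
    .errBadArgument(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]

  hdr_idx <- grepl("^# ", lines)
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^# ([a-zA-Z_]+): *(.*)$", hdr))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    .errMalformedHeader(sprintf("unparseable header line: '%s'",
                                hdr[bad][1L]))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  need <- c("patient", "modality", "prescription_Gy", "fractions",
            "dose_per_fraction_Gy")
  miss <- setdiff(need, keys)
  if (length(miss))
    .errMissingMetadata(sprintf("missing prescription metadata: %s",
                                paste(miss, collapse = ", ")))
  h <- stats::setNames(vals, keys)
  mod <- h[["modality"]]
  if (!mod %in% .MODALITIES)
    .errMalformedHeader(sprintf("unknown modality '%s'", mod))
  presc <- suppressWarnings(as.numeric(h[["prescription_Gy"]]))
  nfx <- suppressWarnings(as.numeric(h[["fractions"]]))
  dpf <- suppressWarnings(as.numeric(h[["dose_per_fraction_Gy"]]))
  if (anyNA(c(presc, nfx, dpf)))
    .errMalformedHeader("non-numeric prescription metadata")

  body <- lines[!hdr_idx]
  block_start <- grep("^## structure:", body)
  if (!length(block_start))
    .errMalformedHeader("no '## structure:' blocks found")
  block_end <- c(block_start[-1L] - 1L, length(body))
  curves <- list()
  for (b in seq_along(block_start)) {
    blk <- body[block_start[b]:block_end[b]]
    meta <- grepl("^## ", blk)
    mkv <- regmatches(blk[meta], regexec("^## ([a-zA-Z_0-9]+): *(.*)$",
                                         blk[meta]))
    if (any(vapply(mkv, length, integer(1)) != 3L))
      .errMalformedHeader("unparseable structure header line")
    mk <- stats::setNames(vapply(mkv, `[`, character(1), 3L),
                          vapply(mkv, `[`, character(1), 2L))
    for (k in c("structure", "volume_cm3", "kind"))
      if (!k %in% names(mk))
        .errMissingMetadata(sprintf("structure block lacks '%s'", k))
    vol <- suppressWarnings(as.numeric(mk[["volume_cm3"]]))
    if (is.na(vol) || vol <= 0)
      .errMalformedHeader("volume_cm3 must be a positive number")
    kind <- mk[["kind"]]
    if (!kind %in% c("cumulative", "differential"))
      .errMalformedHeader(sprintf("unknown kind '%s'", kind))
    rows <- blk[!meta]
    if (!length(rows))
      .errMalformedHeader(sprintf("structure '%s' has no data rows",
                                  mk[["structure"]]))
    parts <- strsplit(rows, ",", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) != 2L))
      .errMalformedHeader("data rows must be 'dose_Gy,relative_volume'")
    num <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE))
    if (anyNA(num))
      .errMalformedHeader("non-numeric data row")
    dose <- num[, 1L]
    rv <- num[, 2L]
    if (any(rv < 0))
      .errNegativeVolume(sprintf("negative volume in structure '%s'",
                                 mk[["structure"]]))
    if (kind == "cumulative" && length(rv) > 1L && any(diff(rv) > .VOL_TOL))
      .errNonMonotone(sprintf(
        "cumulative volume increases in structure '%s'", mk[["structure"]]))
    if (kind == "differential") {
      # rows are (lower bin edge, bin fraction); last row closes the grid
      rv <- rv[-length(rv)]
    }
    curves[[mk[["structure"]]]] <- dvhCurve(
      dose, rv, kind = kind, structure = mk[["structure"]],
      patientID = h[["patient"]], modality = mod, absVolume = vol)
  }
  planSet(curves, patientID = h[["patient"]], modality = mod,
          prescriptionDose = presc, nFractions = nfx, dosePerFraction = dpf)
}

#' @rdname readDVHFile
#' @export
writeDVHFile <- function(plan, path) {
  stopifnot(is(plan, "PlanSet"))
  validObject(plan)
  out <- c(
    sprintf("# patient: %s", plan@patientID),
    sprintf("# modality: %s", plan@modality),
    sprintf("# prescription_Gy: %.6f", plan@prescriptionDose),
    sprintf("# fractions: %g", plan@nFractions),
    sprintf("# dose_per_fraction_Gy: %.6f", plan@dosePerFraction)
  )
  for (cv in plan@curves) {
    out <- c(out,
      sprintf("## structure: %s", cv@structure),
      sprintf("## volume_cm3: %.6f", cv@absVolume),
      sprintf("## kind: %s", cv@kind))
    if (cv@kind == "cumulative") {
      out <- c(out, sprintf("%.6f,%.6f", cv@doseEdges, cv@relVolume))
    } else {
      # differential rows are (lower bin edge, bin fraction); the final edge
      # closes the last bin
      n <- length(cv@doseEdges)
      out <- c(out,
               sprintf("%.6f,%.6f", cv@doseEdges[-n], cv@relVolume),
               sprintf("%.6f,%.6f", cv@doseEdges[n], 0))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

#' Read every DVH file in a directory
#'
#' Reads all \code{*.dvh} files under \code{dir} into a list of
#' [PlanSet-class] objects named \code{<patient>_<modality>}.
#'
#' @param dir directory containing \code{.dvh} files.
#' @return Named list of [PlanSet-class].
#' @export
readDVHDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dvh$", full.names = TRUE))
  if (!length(files))
    .errBadArgument(sprintf("no .dvh files under %s", dir))
  plans <- lapply(files, readDVHFile)
  names(plans) <- vapply(plans, function(p)
    paste(p@patientID, p@modality, sep = "_"), character(1))
  plans
}
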