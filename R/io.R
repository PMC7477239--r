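#' Write a segmented ONH volume to the interchange format
#'
#' One JSON document per volume holding the scan geometry, axial convention
#' and the BMO ring, plus two TSV sidecar matrices (`<stem>_ilm.tsv`,
#' `<stem>_lc.tsv`) with heights serialised at full double precision
#' (`%.17g`) and missing values written as `NA`. Write followed by read
#' reproduces every field bit-exactly.
#'
#' @param volume A [segmented_onh_volume()].
#' @param path Path of the JSON file to write (sidecars are placed next to
#'   it).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "segmented_onh_volume"))
  stem <- sub("\\.json$", "", path)
  ilm_file <- paste0(basename(stem), "_ilm.tsv")
  lc_file <- paste0(basename(stem), "_lc.tsv")
  g <- volume$geometry
  doc <- list(
    format = "onh-volume",
    schema_version = 1L,
    geometry = list(n_bscans = g$n_bscans, n_ascans = g$n_ascans,
                    bscan_spacing = g$bscan_spacing,
                    ascan_spacing = g$ascan_spacing,
                    axial_unit = g$axial_unit),
    axial_convention = volume$axial_convention,
    axial_range = volume$axial_range,
    bmo_points = unname(apply(volume$bmo_points, 1L, as.numeric,
                              simplify = FALSE)),
    ilm_file = ilm_file,
    lc_file = lc_file
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  write_height_tsv(volume$ilm_height, file.path(dirname(path), ilm_file))
  write_height_tsv(volume$lc_height, file.path(dirname(path), lc_file))
  invisible(path)
}

#' Read a segmented ONH volume from the interchange format
#'
#' @param path Path of the JSON file written by [write_volume()].
#' @return A [segmented_onh_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "onh-volume"))
    stop("read_volume: format error at $format: expected \"onh-volume\"",
         call. = FALSE)
  if (!identical(as.integer(doc$schema_version), 1L))
    stop("read_volume: format error at $schema_version: unsupported version",
         call. = FALSE)
  need <- c("geometry", "bmo_points", "ilm_file", "lc_file")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("read_volume: format error at $", miss[1L], ": missing field",
         call. = FALSE)
  gfields <- c("n_bscans", "n_ascans", "bscan_spacing", "ascan_spacing")
  gm <- setdiff(gfields, names(doc$geometry))
  if (length(gm))
    stop("read_volume: format error at $geometry$", gm[1L], ": missing field",
         call. = FALSE)
  geometry <- scan_geometry(doc$geometry$n_bscans, doc$geometry$n_ascans,
                            doc$geometry$bscan_spacing,
                            doc$geometry$ascan_spacing)
  ring <- doc$bmo_points
  if (length(ring) < 8L)
    stop("read_volume: format error at $bmo_points: BMO ring needs at least 8 points",
         call. = FALSE)
  bad <- which(vapply(ring, function(p) length(p) != 3L ||
                        !all(vapply(p, is.numeric, logical(1))), logical(1)))
  if (length(bad))
    stop("read_volume: format error at $bmo_points[", bad[1L],
         "]: expected [x, y, z] numeric triple", call. = FALSE)
  pts <- do.call(rbind, lapply(ring, as.numeric))
  ilm_path <- file.path(dirname(path), doc$ilm_file)
  lc_path <- file.path(dirname(path), doc$lc_file)
  for (p in c(ilm_path, lc_path)) {
    if (!file.exists(p))
      stop("read_volume: missing TSV sidecar: ", p, call. = FALSE)
  }
  ilm <- read_height_tsv(ilm_path, geometry)
  lc <- read_height_tsv(lc_path, geometry)
  axial_range <- if (!is.null(doc$axial_range))
    as.numeric(unlist(doc$axial_range)) else NULL
  segmented_onh_volume(geometry, ilm, lc, pts, axial_range = axial_range)
}

write_height_tsv <- function(height, path) {
  txt <- matrix(sprintf("%.17g", height), nrow(height), ncol(height))
  txt[!is.finite(height)] <- "NA"
  lines <- apply(txt, 1L, paste, collapse = "\t")
  writeLines(lines, path)
}

read_height_tsv <- function(path, geometry) {
  lines <- readLines(path)
  if (length(lines) != geometry$n_bscans)
    stop("read_volume: format error in ", basename(path), ": expected ",
         geometry$n_bscans, " rows, found ", length(lines), call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_found <- lengths(cells)
  if (any(ncol_found != geometry$n_ascans)) {
    r <- which(ncol_found != geometry$n_ascans)[1L]
    stop("read_volume: format error in ", basename(path), " row ", r,
         ": expected ", geometry$n_ascans, " columns, found ", ncol_found[r],
         call. = FALSE)
  }
  m <- matrix(NA_real_, geometry$n_bscans, geometry$n_ascans)
  for (r in seq_along(cells)) {
    v <- cells[[r]]
    isna <- v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!isna & is.na(num))
    if (length(bad))
      stop("read_volume: format error in ", basename(path), " row ", r,
           " column ", bad[1L], ": non-numeric token \"", v[bad[1L]], "\"",
           call. = FALSE)
    m[r, ] <- num
  }
  m
}

#' Write / read a cohort table as CSV
#'
#' Header: `primate_id,eye,group,treatment,month,mean_iop,max_iop,mrw,lcd`.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly. `read_cohort_csv`: a
#'   `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("primate_id", "eye", "group", "treatment", "month",
            "mean_iop", "max_iop", "mrw", "lcd")
  stopifnot(all(cols %in% names(cohort)))
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("read_cohort_csv: file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("primate_id", "eye", "group", "treatment", "month",
            "mean_iop", "max_iop", "mrw", "lcd")
  miss <- setdiff(cols, names(out))
  if (length(miss))
    stop("read_cohort_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
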