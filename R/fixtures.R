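# Pinned checksums of the packaged per-animal study tables; any edit to the
# transcribed values fails the fixture-integrity test.
FIXTURE_MD5 <- c(
  table1_iop = "a894750e11fcd6f3b685e511bad7cfa3",
  table2_morphometry = "e836aa0cf2d40cea39d191cedf16740e"
)

#' Load a packaged per-animal study table
#'
#' `table1_iop`: one row per animal (16 rows) with baseline IOP, injection
#' counts, weeks to IOP elevation, and months-2-to-7 mean and maximum IOP per
#' eye (columns suffixed `_od`/`_os`; `_sd` columns hold the printed
#' per-animal SDs, whose averaging basis across readings is not redefined
#' here).
#'
#' `table2_morphometry`: long format, one row per animal x eye x timepoint
#' (64 rows) with mean MRW and LCD (um) at baseline and month 7.
#'
#' @param name `"table1_iop"` or `"table2_morphometry"`.
#' @return A data frame.
#' @export
#' @examples
#' t1 <- load_fixture("table1_iop")
#' group_summary(t1, "mean_iop_m2_7", group = 2, eye = "OD")$mean  # 31.0
load_fixture <- function(name = c("table1_iop", "table2_morphometry")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("table1_iop", "table2_morphometry"))
    stop("load_fixture: unknown fixture '", paste(name, collapse = ","), "'",
         call. = FALSE)
  path <- fixture_path(name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

fixture_path <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "onhmorph")
  if (!nzchar(path))
    stop("load_fixture: packaged fixture not found: ", name, call. = FALSE)
  path
}

#' Verify the integrity of the packaged fixtures
#'
#' Compares MD5 checksums of the installed fixture files against the values
#' pinned at packaging time.
#'
#' @return Named logical vector, `TRUE` where the checksum matches.
#' @export
verify_fixtures <- function() {
  vapply(names(FIXTURE_MD5), function(nm) {
    unname(tools::md5sum(fixture_path(nm))) == FIXTURE_MD5[[nm]]
  }, logical(1))
}
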