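# md5 sums of the packaged fixture files, checked at every load
.fixture_md5 <- c(
  table1 = "4155b3de518b4361f311214cbdcdfeaa",
  table4 = "9e68ef1618b777516b6444903cff20a6"
)

.fixture_file <- c(
  table1 = "table1_cohort.csv",
  table4 = "table4_results.csv"
)

#' Load a bundled cohort fixture
#'
#' Two per-patient tables from a published 10-patient virtual aortic valve
#' replacement study ship with the package:
#'
#' * `"table1"` — patient characteristics: sex, aortic regurgitation class,
#'   height, weight, body surface area, age, reference valve label size,
#'   peak systolic flow rate used as the simulation boundary condition, and
#'   post-surgery clinical parameters (10 rows).
#' * `"table4"` — per-patient peak transvalvular gradient (mmHg) and
#'   normalized flow displacement for three valve sizes (one smaller than
#'   the implanted reference, the reference, one larger) at rest and under
#'   simulated physical stress, unpivoted to one row per
#'   (patient, size class, state) cell (60 rows).
#'
#' File integrity is verified against a stored checksum at load time.
#'
#' @param name `"table1"` or `"table4"`.
#' @return A data frame.
#' @export
load_fixture <- function(name = c("table1", "table4")) {
  if (length(name) != 1L || !name %in% names(.fixture_file)) {
    stop("load_fixture: unknown fixture; use \"table1\" or \"table4\"",
         call. = FALSE)
  }
  path <- system.file("extdata", .fixture_file[[name]], package = "vavr",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]]))) {
    stop("load_fixture: checksum mismatch for ", .fixture_file[[name]],
         " (file corrupted?)", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "table4" && nrow(df) != 60L) {
    stop("load_fixture: table4 must have 60 rows (10 patients x 3 sizes x ",
         "2 states)", call. = FALSE)
  }
  df
}
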