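#' Bundled Canadian pediatric life table (2022, both sexes)
#'
#' Age-specific annual all-cause death probabilities for ages 0 to 25,
#' transcribed to pediatric precision from Statistics Canada life tables
#' (Table 13-10-0114-01, 2020-2022, both sexes). The file ships as a
#' synthetic transcription rather than a verbatim extract of the published
#' table; values carry the order of magnitude (about 1e-4 to 5e-3 across
#' these ages) the model is sensitive to. Covers both the default start age
#' of 1 year and the start-age-0 scenario over the 20-year horizon.
#'
#' @return A `life_table` data.frame with columns `age` and `q_annual`.
#' @export
#' @examples
#' lt <- bundled_life_table()
#' range(lt$q_annual)
bundled_life_table <- function() {
  path <- system.file("extdata", "canada_life_table_2022_synthetic.csv",
                      package = "epiwait", mustWork = TRUE)
  read_life_table(path)
}

#' Read a life table from a two-column CSV
#'
#' Strict parser: the file must have a header `age,q_annual`, integer ages
#' contiguous from the minimum age, and probabilities in \[0, 1\]. Anything
#' non-numeric is an error.
#'
#' @param path Path to the CSV file.
#' @return A `life_table` data.frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(df), c("age", "q_annual")))
    stop("life table must have columns 'age' and 'q_annual'")
  as_life_table(df)
}

#' Write a life table to CSV
#' @param lt A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

as_life_table <- function(df) {
  if (anyNA(df$age) || anyNA(df$q_annual)) stop("life table contains NA")
  if (any(df$age != as.integer(df$age))) stop("ages must be integers")
  if (!identical(as.integer(df$age), seq(min(df$age), max(df$age))))
    stop("ages must be contiguous")
  if (any(df$q_annual < 0 | df$q_annual > 1))
    stop("q_annual must lie in [0,1]")
  structure(df, class = c("life_table", "data.frame"))
}

#' Annual death probability at a given age
#'
#' @param lt A `life_table`.
#' @param age Integer age in years.
#' @return The annual probability of death within the year of that age.
#' @export
life_table_q <- function(lt, age) {
  i <- match(age, lt$age)
  if (anyNA(i)) stop("age ", paste(age[is.na(i)], collapse = ", "),
                     " outside life-table coverage [", min(lt$age), ",",
                     max(lt$age), "]")
  lt$q_annual[i]
}

#' Synthetic life table with geometric age trend
#'
#' Deterministic generator for property tests:
#' `q(age) = min(1, base_q * (1 + growth)^age)` over ages 0 to `max_age`.
#'
#' @param seed Integer seed (kept for interface symmetry; the table is a
#'   closed form of its arguments).
#' @param base_q Annual death probability at age 0, in \[0, 1).
#' @param growth Proportional increase per year of age, >= 0.
#' @param max_age Last covered age (default 25).
#' @return A `life_table`.
#' @export
synthetic_life_table <- function(seed, base_q, growth, max_age = 25) {
  if (!is.finite(base_q) || base_q < 0 || base_q >= 1)
    stop("base_q must be in [0,1)")
  if (growth < 0) stop("growth must be >= 0")
  ages <- 0:max_age
  as_life_table(data.frame(age = ages,
                           q_annual = pmin(1, base_q * (1 + growth)^ages)))
}

#' Random plausible parameter set
#'
#' Draws a full parameter set from the probabilistic-sensitivity-analysis
#' distribution families (beta for probabilities and utilities, gamma for
#' costs, lognormal for hospital length of stay), reproducible by seed, with
#' every derived field re-derived. Used to exercise every downstream stage
#' on inputs other than the base case.
#'
#' @param seed Integer seed.
#' @return A valid `ww_parameters` object.
#' @export
synthetic_parameters <- function(seed) {
  set.seed(seed)
  sample_psa_draw(default_parameters())
}
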