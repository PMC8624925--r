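#' Read a droplet CSV
#'
#' Dialect: UTF-8, comma-separated, decimal point, header
#' `well,sample_id,positives,total,dna_ng`, one row per well. The vendor
#' column names `Well`, `Sample`, `Positives`/`PositiveDroplets`, and
#' `AcceptedDroplets` are mapped onto the dialect when present.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `well_id`, `sample_id`, `positives`,
#'   `total`, `dna_ng` and a logical `saturated` column; every row
#'   validated, errors name the offending row.
#' @export
read_droplet_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("droplet file '%s' does not exist", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) {
    stop(sprintf("droplet file '%s': no records", path), call. = FALSE)
  }
  aliases <- c(
    well = "well_id", Well = "well_id",
    Sample = "sample_id", SampleID = "sample_id",
    Positives = "positives", PositiveDroplets = "positives",
    AcceptedDroplets = "total", Total = "total",
    DNA_ng = "dna_ng"
  )
  for (a in names(aliases)) {
    if (a %in% names(df) && !(aliases[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- aliases[[a]]
    }
  }
  needed <- c("well_id", "sample_id", "positives", "total", "dna_ng")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(
      sprintf(
        "droplet file '%s' lacks column(s): %s", path,
        paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  for (col in c("positives", "total", "dna_ng")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(
        sprintf(
          "droplet file '%s', row %d: non-numeric '%s'", path, bad[1],
          col
        ),
        call. = FALSE
      )
    }
    df[[col]] <- v
  }
  bad <- which(df$positives > df$total)
  if (length(bad)) {
    stop(
      sprintf(
        "droplet file '%s', row %d: positives (%g) exceed total (%g)",
        path, bad[1], df$positives[bad[1]], df$total[bad[1]]
      ),
      call. = FALSE
    )
  }
  bad <- which(df$total <= 0)
  if (length(bad)) {
    stop(sprintf("droplet file '%s', row %d: total must be > 0", path, bad[1]),
      call. = FALSE
    )
  }
  bad <- which(df$positives < 0 | df$dna_ng < 0)
  if (length(bad)) {
    stop(
      sprintf(
        "droplet file '%s', row %d: negative positives or dna_ng",
        path, bad[1]
      ),
      call. = FALSE
    )
  }
  out <- data.frame(
    well_id = as.character(df$well_id),
    sample_id = as.character(df$sample_id),
    positives = as.integer(df$positives),
    total = as.integer(df$total),
    dna_ng = df$dna_ng,
    saturated = df$positives == df$total,
    stringsAsFactors = FALSE
  )
  out
}

#' Write a droplet CSV in the package dialect
#'
#' @param droplets Data frame with the droplet-dialect columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(droplets, path) {
  cols <- c("well_id", "sample_id", "positives", "total", "dna_ng")
  utils::write.csv(as.data.frame(droplets)[, cols],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns `sample_id` and `dna_ng`; sample ids must be unique, masses
#' positive.
#'
#' @param path Path to the CSV sample sheet.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!all(c("sample_id", "dna_ng") %in% names(df))) {
    stop(sprintf("sample sheet '%s' needs columns sample_id, dna_ng", path),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("sample sheet '%s': duplicated sample ids", path),
      call. = FALSE
    )
  }
  df$dna_ng <- as.numeric(df$dna_ng)
  if (any(is.na(df$dna_ng)) || any(df$dna_ng <= 0)) {
    stop(sprintf("sample sheet '%s': dna_ng must be numeric and > 0", path),
      call. = FALSE
    )
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a population-rule file
#'
#' JSON with keys `mean_cpn`, `sd_cpn` and optionally `z` (default 1.96).
#'
#' @param path Path to the rule file.
#' @return A [population_rule()].
#' @export
read_population_rule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$mean_cpn) || is.null(obj$sd_cpn)) {
    stop(sprintf("rule file '%s' needs keys mean_cpn and sd_cpn", path),
      call. = FALSE
    )
  }
  population_rule(
    as.numeric(obj$mean_cpn), as.numeric(obj$sd_cpn),
    if (is.null(obj$z)) 1.96 else as.numeric(obj$z)
  )
}

#' Write a screening report CSV and log a category summary
#'
#' Deterministic column order; purity reported as a percentage rounded to 4
#' significant digits. A summary line
#' `"N non-suspicious / M suspicious"` is emitted via [message()].
#'
#' @param results A [percent_purity()] result (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("no results to report", call. = FALSE)
  out <- data.frame(
    sample_id = results$sample_id,
    cm = signif(results$cm, 6),
    ce = signif(results$ce, 6),
    lCe = signif(results$lCe, 6),
    uCe = signif(results$uCe, 6),
    purity_pct = signif(100 * results$purity, 4),
    category = results$category,
    tier = results$tier,
    flags = ifelse(isTRUE(results$below_range) | results$below_range %in% TRUE,
      "below_quantification_range", ""
    ),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  n_ok <- sum(results$category == "non_suspicious", na.rm = TRUE)
  n_sus <- sum(results$category == "suspicious", na.rm = TRUE)
  message(sprintf("%d non-suspicious / %d suspicious", n_ok, n_sus))
  invisible(path)
}
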