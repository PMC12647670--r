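#' Read a table of species-description records
#'
#' Reads a CSV or TSV file with one row per species description and columns
#' `group`, `species`, `year`, `authors` (author names joined with
#' semicolons). Rows with an unparseable or out-of-range year, or an empty
#' species name, are rejected with a warning that lists their line numbers;
#' duplicated (`group`, `species`) pairs keep the first occurrence, with a
#' warning (database exports frequently contain residual duplicate names; no
#' synonymy resolution is attempted).
#'
#' @param path Path to a delimited file; `.tsv`/`.tab` extensions are read as
#'   tab-separated, everything else as comma-separated.
#' @param end_year Last acceptable description year (default 2017; the year
#'   grid always starts in 1753).
#' @return A tibble with columns `group`, `species`, `year` (integer) and
#'   `authors` (semicolon-joined string).
#' @export
read_description_table <- function(path, end_year = 2017L) {
  reader <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- suppressWarnings(
    reader(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
  )
  need <- c("group", "species", "year", "authors")
  if (!all(need %in% names(raw))) {
    abort(
      paste0(
        "Description table must have columns ",
        paste(need, collapse = ", "), "."
      ),
      class = "descurves_error_ingest"
    )
  }
  if (nrow(raw) == 0) {
    abort("Description table is empty.", class = "descurves_error_ingest")
  }
  raw <- raw[need]
  raw$species <- trimws(raw$species)
  raw$group <- trimws(raw$group)
  yr <- suppressWarnings(as.integer(trimws(raw$year)))
  bad_year <- is.na(yr) | yr < START_YEAR | yr > end_year
  bad_species <- is.na(raw$species) | raw$species == ""
  bad <- bad_year | bad_species
  if (any(bad)) {
    warn(paste0(
      sum(bad), " malformed row(s) rejected (line ",
      paste(which(bad) + 1L, collapse = ", "),
      "): year must be an integer in ", START_YEAR, "-", end_year,
      " and species must be nonempty."
    ))
  }
  out <- tibble(
    group = raw$group[!bad],
    species = raw$species[!bad],
    year = yr[!bad],
    authors = raw$authors[!bad]
  )
  if (nrow(out) == 0) {
    abort("No valid description records in file.",
      class = "descurves_error_ingest"
    )
  }
  dup <- duplicated(out[c("group", "species")])
  if (any(dup)) {
    warn(paste0(
      sum(dup), " duplicated (group, species) row(s); keeping first occurrence."
    ))
    out <- out[!dup, ]
  }
  out
}

#' Write description records to a TSV file
#'
#' Inverse of [read_description_table()]; columns `group`, `species`, `year`,
#' `authors` (semicolon-joined).
#'
#' @param records Tibble of description records.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_description_table <- function(records, path) {
  readr::write_tsv(records[c("group", "species", "year", "authors")], path,
    progress = FALSE
  )
  invisible(path)
}

#' Build the yearly and cumulative description series for one group
#'
#' Counts descriptions per calendar year on the inclusive 1753–`end_year`
#' grid (years without descriptions are explicit zeros), accumulates them,
#' and scales the cumulative by its final value so curves of groups with very
#' different richness are comparable on \[0,1\].
#'
#' @param records Tibble from [read_description_table()] (or equivalent).
#' @param group Group label to extract.
#' @param end_year Last year of the grid.
#' @return A tibble with columns `group`, `year`, `count`, `cumulative`,
#'   `scaled`.
#' @export
build_yearly_series <- function(records, group, end_year = 2017L) {
  rec <- records[records$group == group, ]
  if (nrow(rec) == 0) {
    abort(
      paste0(
        "Unknown group '", group, "'. Available: ",
        paste(sort(unique(records$group)), collapse = ", ")
      ),
      class = "descurves_error_unknown_group"
    )
  }
  yrs <- year_grid(end_year)
  counts <- tabulate(match(rec$year, yrs), nbins = length(yrs))
  cum <- cumsum(counts)
  fin <- cum[length(cum)]
  tibble(
    group = group,
    year = yrs,
    count = as.integer(counts),
    cumulative = as.integer(cum),
    scaled = if (fin > 0) cum / fin else rep(0, length(yrs))
  )
}

## Normalise an author name for equality: trim whitespace, case-fold.
normalise_author <- function(x) tolower(trimws(x))

#' Mean number of unique describing authors per year
#'
#' For each year of the 1753–`end_year` grid, counts the distinct author
#' names (exact match after whitespace trimming and case folding) appearing
#' on that year's descriptions, and averages the counts over all years of the
#' grid (`method = "per_year"`, the default). `method = "pooled"` instead
#' divides the number of distinct author names over the whole period by the
#' number of years; the phrasing used in the field admits both readings, and
#' the per-year reading is the default.
#'
#' @inheritParams build_yearly_series
#' @param method `"per_year"` or `"pooled"` (see Details).
#' @return A single numeric value (authors per year).
#' @export
mean_authors_per_year <- function(records, group, end_year = 2017L,
                                  method = c("per_year", "pooled")) {
  method <- match.arg(method)
  rec <- records[records$group == group, ]
  if (nrow(rec) == 0) {
    abort(
      paste0(
        "Unknown group '", group, "'. Available: ",
        paste(sort(unique(records$group)), collapse = ", ")
      ),
      class = "descurves_error_unknown_group"
    )
  }
  yrs <- year_grid(end_year)
  rec <- rec[rec$year %in% yrs, ]
  split_authors <- strsplit(rec$authors %||% "", ";", fixed = TRUE)
  split_authors <- lapply(split_authors, normalise_author)
  if (method == "pooled") {
    total <- length(unique(unlist(split_authors)))
    return(total / length(yrs))
  }
  per_year <- vapply(yrs, function(y) {
    length(unique(unlist(split_authors[rec$year == y])))
  }, numeric(1))
  mean(per_year)
}

#' Relabel groups (e.g. aggregate insect orders into Insecta)
#'
#' Applies a label mapping to description records, so analyses can be re-run
#' at a coarser taxonomic level. Labels not named in the mapping pass through
#' unchanged. Chained mappings (an old label mapped onto a label that is
#' itself remapped elsewhere) are rejected as ambiguous.
#'
#' @param records Tibble of description records.
#' @param mapping Named character vector, `old label -> new label`.
#' @return The records with relabelled `group`.
#' @export
aggregate_groups <- function(records, mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("`mapping` must be a named character vector (old -> new).",
      class = "descurves_error_mapping"
    )
  }
  non_identity <- mapping[names(mapping) != mapping]
  chained <- unname(non_identity) %in% names(non_identity)
  if (any(chained)) {
    abort(
      paste0(
        "Cyclic or conflicting mapping: target label(s) ",
        paste(unique(non_identity[chained]), collapse = ", "),
        " are themselves remapped."
      ),
      class = "descurves_error_mapping"
    )
  }
  hit <- records$group %in% names(mapping)
  records$group[hit] <- unname(mapping[records$group[hit]])
  records
}

#' Min-max scale numeric columns to the unit interval
#'
#' Scales each selected column with `x -> (x - min) / (max - min)` and stores
#' the per-column `(min, max)` as attribute `"scaling"` so the transform can
#' be inverted with [unscale_unit_interval()]. Path-model predictors and
#' curve parameters are scaled this way before fitting, which stabilises the
#' model across groups whose raw scales differ by orders of magnitude.
#'
#' @param data A data frame.
#' @param cols Character vector of columns to scale; default: all numeric
#'   columns.
#' @return The scaled tibble with attribute `"scaling"` (a tibble of
#'   `column`, `min`, `max`).
#' @export
scale_unit_interval <- function(data, cols = NULL) {
  data <- as_tibble(data)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  mins <- vapply(data[cols], min, numeric(1))
  maxs <- vapply(data[cols], max, numeric(1))
  const <- maxs <= mins
  if (any(const)) {
    abort(
      paste0(
        "Constant column(s) cannot be scaled to [0,1]: ",
        paste(cols[const], collapse = ", ")
      ),
      class = "descurves_error_constant_column"
    )
  }
  for (i in seq_along(cols)) {
    data[[cols[i]]] <- (data[[cols[i]]] - mins[i]) / (maxs[i] - mins[i])
  }
  attr(data, "scaling") <- tibble(column = cols, min = mins, max = maxs)
  data
}

#' Invert a min-max scaling
#'
#' @param data A tibble previously scaled by [scale_unit_interval()].
#' @param scaling Scaling metadata; defaults to the `"scaling"` attribute.
#' @return The tibble on the original scales.
#' @export
unscale_unit_interval <- function(data, scaling = attr(data, "scaling")) {
  if (is.null(scaling)) {
    abort("No scaling metadata found.", class = "descurves_error_params")
  }
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$column[i]
    data[[cl]] <- data[[cl]] * (scaling$max[i] - scaling$min[i]) +
      scaling$min[i]
  }
  attr(data, "scaling") <- NULL
  data
}

#' Packaged 47-group predictor and curve-parameter table
#'
#' A compiled table for the 47 major eukaryote lineages analysed on the
#' 1753–2017 description-year grid: per group, the current number of
#' described species, mean unique describing authors per year, a
#' literature-corpus public-interest count, body-size class (exponent of mm
#' to base 10, in -3..2), ordinal (1–5) fractions of soil-dwelling or
#' endoparasitic and of aquatic species, the fraction of species with
#' occurrences in Europe, the USA, Canada and Russia, and the fitted
#' half-normal curve parameters (future descriptions ratio, initial
#' description time in years since 1753, curve residual sum of squares in
#' scaled units).
#'
#' @return A 47-row tibble.
#' @export
description_curve_fixture <- function() {
  path <- system.file("extdata", "tables_2_3_fixture.csv",
    package = "descurves", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      group = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
}
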