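#' Percentage with half-away-from-zero rounding
#'
#' `round(100 * count / total, decimals)` with ties rounded away from zero
#' (the convention behind printed figures like 57.4 or 11.3), not the
#' IEEE round-half-even used by [base::round()].
#'
#' @param count Non-negative integer, `count <= total`.
#' @param total Positive integer.
#' @param decimals Number of decimals (default 1).
#' @return Numeric percentage.
#' @export
percentage <- function(count, total, decimals = 1L) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must lie in [0, total]")
  x <- 100 * count / total
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Compile a pipeline report
#'
#' Aggregates available stage outputs into one schema-versioned bundle
#' with deterministic serialization (sorted keys). Missing stages yield
#' `NULL` fields. Spacer totals quoted by different stages must agree.
#'
#' @param defense Optional list with `matrix` ([phylum_defense_matrix()]),
#'   `assignments`.
#' @param cas Optional list with `modules`, `stats` ([cas_abundance_stats()]).
#' @param crispr Optional list with `arrays`, `spacers`, `histogram`,
#'   `majority_cutoff`.
#' @param match Optional list with `matches`, `summary` ([match_summary()]).
#' @param network Optional list with `n_nodes`, `n_edges`, `n_components`,
#'   `category_counts`.
#' @param config Effective configuration snapshot (list).
#' @param label Dataset label.
#' @return A list of class `"defenscan_report"`.
#' @export
compile_report <- function(defense = NULL, cas = NULL, crispr = NULL,
                           match = NULL, network = NULL,
                           config = list(), label = "dataset") {
  if (!is.null(crispr) && !is.null(match) && nrow(match$matches) > 0) {
    n_sp <- nrow(crispr$spacers)
    bad <- setdiff(unique(match$matches$spacer_id), crispr$spacers$spacer_id)
    if (length(bad)) {
      stop("inconsistent stage outputs: matched spacer ids absent from the ",
           "CRISPR stage spacer table (fields: match$matches$spacer_id vs ",
           "crispr$spacers$spacer_id)")
    }
    if (sum(crispr$arrays$size) != n_sp) {
      stop("inconsistent stage outputs: sum of array sizes != spacer count ",
           "(fields: crispr$arrays$size vs crispr$spacers)")
    }
  }
  rep <- list(
    schema_version = "1.0",
    label = label,
    config = config,
    defense = if (!is.null(defense)) list(
      n_defense_genes = nrow(defense$assignments),
      n_assigned = sum(defense$assignments$status == "assigned"),
      n_ambiguous = sum(defense$assignments$status == "ambiguous"),
      per_system = as.list(
        tapply(defense$assignments$status == "assigned",
               defense$assignments$system, sum, default = 0L)),
      pct_defense_of_all_genes = percentage(
        nrow(defense$assignments), sum(defense$matrix$phylum_total_genes)),
      matrix_long = defense$matrix_long
    ),
    cas = if (!is.null(cas)) list(
      n_modules = nrow(cas$modules),
      n_classified = sum(cas$modules$type != "unclassified"),
      type_distribution = cas$stats$type_distribution,
      subtype_distribution = cas$stats$subtype_distribution
    ),
    crispr = if (!is.null(crispr)) list(
      n_arrays = nrow(crispr$arrays),
      n_spacers = nrow(crispr$spacers),
      mean_spacer_length = if (nrow(crispr$spacers)) mean(nchar(crispr$spacers$sequence)) else NULL,
      mean_array_size = if (nrow(crispr$arrays)) mean(crispr$arrays$size) else NULL,
      size_histogram = crispr$histogram,
      majority_cutoff = crispr$majority_cutoff
    ),
    match = if (!is.null(match)) list(
      n_matches = nrow(match$matches),
      summary = match$summary
    ),
    network = network
  )
  # drop NULLs, sort keys for deterministic serialization
  rep <- rep[!vapply(rep, is.null, logical(1))]
  rep <- rep[order(names(rep))]
  structure(rep, class = "defenscan_report")
}

#' Write a report to JSON (+ figure-ready TSVs)
#'
#' @param report A `"defenscan_report"` from [compile_report()].
#' @param dir Output directory (created if missing).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  if (!is.null(report$defense$matrix_long)) {
    utils::write.table(report$defense$matrix_long,
                       file.path(dir, "fig_defense_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$crispr$size_histogram)) {
    utils::write.table(report$crispr$size_histogram,
                       file.path(dir, "fig_array_sizes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Validate a report against the shipped schema
#'
#' Structural check of required fields and types against the JSON schema
#' shipped in `extdata/report_schema.json`.
#'
#' @param report A `"defenscan_report"` or a path to a report JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "defenscan", mustWork = TRUE))
  req <- unlist(schema$required)
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report missing required field(s): ",
                         paste(miss, collapse = ", "))
  if (!identical(as.character(report$schema_version), "1.0")) {
    stop("unsupported report schema_version")
  }
  invisible(TRUE)
}
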