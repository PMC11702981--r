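#' Catalog of packaged fixtures
#'
#' Small plain-text fixtures shipped under `inst/extdata`: the worked
#' mutant-allele-fraction examples, the four-gene RPS signature as GMT,
#' the tiny expression matrices used by the scoring oracles, a template
#' documenting the candidate-list schema, and the default synthetic-cohort
#' preset.
#'
#' @return Tibble with `name`, `file` and `description`; every listed file
#'   exists in the installed package.
#' @examples
#' list_fixtures()
#' @export
list_fixtures <- function() {
  cat_ <- tibble(
    name = c("maf_worked_examples", "rps_signature", "ssgsea_oracle_6x2",
             "gsva_oracle_8x4", "candidate_template", "cohort_preset"),
    file = c("maf_worked_examples.tsv", "rps.gmt", "ssgsea_oracle_6x2.tsv",
             "gsva_oracle_8x4.tsv", "candidate_template.tsv",
             "cohort_presets.yaml"),
    description = c(
      "Allele counts whose reported MAF percentages are fixed reference points (44/98 -> 45, 35/100 -> 35)",
      "Four-gene DNA-repair chemosensitivity signature (RIF1, F2R, RAD51, XRCC5) in GMT format",
      "6-gene x 2-sample log2-expression fixture for the ssGSEA running-sum oracle",
      "8-gene x 4-sample log2-expression fixture for the GSVA (ecdf kernel) oracle",
      "Schema template for a user-supplied candidate p53-target list (gene, class)",
      "Default synthetic-cohort configuration as YAML"
    )
  )
  cat_$path <- vapply(cat_$file, fixture_path, character(1))
  cat_
}

#' Simulate a cohort from a packaged preset
#'
#' Reads a named configuration from the packaged YAML presets and hands it
#' to [simulate_cohort()].
#'
#' @param name Preset name (`"default"` or `"small"`).
#' @param seed Integer seed.
#' @return A `p53_cohort`.
#' @export
cohort_preset <- function(name = "default", seed = 1) {
  presets <- yaml::read_yaml(fixture_path("cohort_presets.yaml"))
  if (!name %in% names(presets)) {
    abort(paste("unknown preset:", name))
  }
  do.call(simulate_cohort, c(presets[[name]], list(seed = seed)))
}

#' Path to a packaged fixture file
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path; errors if the fixture does not exist.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "p53ces")
  if (p == "") abort(paste("no packaged fixture named", file))
  p
}
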