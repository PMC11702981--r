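#' Read a gene-by-sample expression matrix
#'
#' Reads TSV or CSV (by extension; `.gz` handled transparently) with gene
#' ids in the first column and one numeric column per sample.
#'
#' @param path File path.
#' @param layer Layer tag attached to the result (`"counts"`,
#'   `"log2fpkm"` or `"tpm"`).
#' @return Numeric matrix (genes x samples) with attribute `layer`.
#' @export
read_expression <- function(path, layer = c("counts", "log2fpkm", "tpm")) {
  layer <- match.arg(layer)
  df <- read_delim_auto(path)
  if (ncol(df) < 2 || nrow(df) == 0) abort("empty expression matrix")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort(paste("duplicate gene id(s):", paste(unique(dup), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste("non-numeric sample column(s):", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  attr(m, "layer") <- layer
  m
}

#' Write a gene-by-sample expression matrix as TSV
#'
#' @param mat Numeric matrix with gene row names.
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- bind_cols(tibble(gene = rownames(mat)), as_tibble(mat))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV/CSV with columns `sample`, `group` and optionally `cohort`; groups
#' must be among NT, WT, MM, TM.
#'
#' @param path File path.
#' @return Tibble with `sample`, `group`, `cohort`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("sample", "group") %in% names(df))) {
    abort("sample sheet needs `sample` and `group` columns")
  }
  bad <- setdiff(unique(df$group), c("NT", "WT", "MM", "TM"))
  if (length(bad) > 0) {
    abort(paste("unknown group(s):", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$sample)) abort("duplicate sample ids in sample sheet")
  if (!"cohort" %in% names(df)) df$cohort <- "cohort"
  as_tibble(df[, c("sample", "group", "cohort")])
}

#' Read gene sets from a GMT file
#'
#' Strict GMT dialect: every line is `name<TAB>description<TAB>member...`.
#' A missing description field or an empty member list is an error;
#' repeated members within a set are deduplicated with a warning;
#' duplicate set names are an error.
#'
#' @param path File path (`.gz` accepted).
#' @return Named list of character vectors, with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  descs <- character()
  for (p in parts) {
    if (length(p) < 3) {
      abort(paste0("malformed GMT line for set `", p[1],
                   "`: need name, description and at least one member"))
    }
    name <- p[1]
    if (name %in% names(sets)) abort(paste("duplicate set name:", name))
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) abort(paste("empty gene set:", name))
    if (anyDuplicated(members)) {
      warn(paste("deduplicating repeated member(s) in set", name))
      members <- unique(members)
    }
    sets[[name]] <- members
    descs[name] <- p[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every set needs a name")
  }
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[nm] %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a DR/UR gene-set pair as GMT
#'
#' Emits two sets named `<cohort>_p53tru_DR` and `<cohort>_p53tru_UR`.
#'
#' @param pair A `p53_geneset_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geneset_pair <- function(pair, path) {
  sets <- list(pair$dr, pair$ur)
  names(sets) <- paste0(pair$cohort, c("_p53tru_DR", "_p53tru_UR"))
  write_gmt(sets, path)
}

read_delim_auto <- function(path) {
  stripped <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", stripped, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
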