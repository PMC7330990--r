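#' Column-name dialect for affinity tables
#'
#' Affinity tables arrive in heterogeneous layouts (IEDB exports, curated
#' benchmark files, this package's own canonical dialect). A dialect maps the
#' canonical column roles onto the column names actually present in a file.
#'
#' @param allele,peptide,ic50_nm,inequality,kind Column names in the file for
#'   each canonical role.
#' @return Named character vector of class `affinity_dialect`.
#' @examples
#' affinity_dialect()  # the canonical layout
#' affinity_dialect(allele = "mhc", ic50_nm = "meas")
#' @export
affinity_dialect <- function(allele = "allele", peptide = "peptide",
                             ic50_nm = "ic50_nM", inequality = "inequality",
                             kind = "kind") {
  structure(
    c(allele = allele, peptide = peptide, ic50_nm = ic50_nm,
      inequality = inequality, kind = kind),
    class = "affinity_dialect"
  )
}

ineq_codes <- c("=" = "EQ", "<" = "LT", ">" = "GT",
                "EQ" = "EQ", "LT" = "LT", "GT" = "GT")
kind_codes <- c(
  "quant" = "quantitative", "qual" = "qualitative",
  "quantitative" = "quantitative", "qualitative" = "qualitative"
)

# Validate one parsed row; returns NULL if OK, else a reason string.
affinity_row_problem <- function(peptide, ic50_nm, inequality, kind) {
  if (is.na(peptide) || !nzchar(peptide)) {
    return("empty peptide")
  }
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% amino_acids())
  if (length(bad) > 0L) {
    return(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  if (is.na(inequality)) {
    return("unrecognised inequality qualifier")
  }
  if (is.na(kind)) {
    return("unrecognised measurement kind")
  }
  if (is.na(ic50_nm)) {
    return("unparseable IC50")
  }
  if (ic50_nm <= 0) {
    return("non-positive IC50")
  }
  if (kind == "quantitative" && inequality != "EQ") {
    return("quantitative record must carry inequality '='")
  }
  if (kind == "qualitative" && inequality == "EQ") {
    return("qualitative record must carry inequality '<' or '>'")
  }
  NULL
}

#' Read a peptide-MHC affinity table
#'
#' Parses a delimited (comma or tab; autodetected from the header line)
#' affinity table into a validated tibble of affinity records. Each row is
#' one allele-peptide measurement: a positive IC50 in nM plus an inequality
#' qualifier. Quantitative records carry an exact IC50 (`inequality = "EQ"`);
#' qualitative records are censored measurements where the IC50 column holds
#' the bound (`"LT"`/`"GT"`). Rows that violate the record invariants
#' (unknown residues, unparseable or non-positive IC50, inconsistent
#' kind/inequality) are rejected, never silently dropped: they are returned
#' in the `rejections` attribute with a reason each.
#'
#' @param path Path to the delimited file (header required).
#' @param dialect An [affinity_dialect()] mapping canonical roles to the
#'   file's column names.
#' @return A tibble of class `affinity_tbl` with columns `allele`, `peptide`,
#'   `ic50_nm`, `inequality` (`"EQ"`, `"LT"`, `"GT"`) and `kind`
#'   (`"quantitative"`, `"qualitative"`), plus attribute `rejections`
#'   (a tibble with `row`, `peptide`, `reason`), retrievable with
#'   [rejected_records()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "allele,peptide,ic50_nM,inequality,kind",
#'   "HLA-A-0201,SIINFEKL,120.0,=,quant"
#' ), f)
#' read_affinity_table(f)
#' @export
read_affinity_table <- function(path, dialect = affinity_dialect()) {
  if (!file.exists(path)) {
    stop("affinity table not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(
    path, header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, quote = "\"", comment.char = "", stringsAsFactors = FALSE
  )
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0L) {
    stop("affinity table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  peptide <- toupper(trimws(raw[[dialect[["peptide"]]]]))
  allele <- trimws(raw[[dialect[["allele"]]]])
  ic50 <- suppressWarnings(as.numeric(raw[[dialect[["ic50_nm"]]]]))
  ineq <- unname(ineq_codes[trimws(raw[[dialect[["inequality"]]]])])
  kind <- unname(kind_codes[tolower(trimws(raw[[dialect[["kind"]]]]))])

  problems <- vapply(
    seq_len(nrow(raw)),
    function(i) {
      p <- affinity_row_problem(peptide[i], ic50[i], ineq[i], kind[i])
      if (is.null(p)) NA_character_ else p
    },
    character(1)
  )
  keep <- is.na(problems)
  records <- tibble::tibble(
    allele = allele[keep],
    peptide = peptide[keep],
    ic50_nm = ic50[keep],
    inequality = ineq[keep],
    kind = kind[keep]
  )
  rejections <- tibble::tibble(
    row = which(!keep),
    peptide = raw[[dialect[["peptide"]]]][!keep],
    reason = problems[!keep]
  )
  if (nrow(rejections) > 0L) {
    message(sprintf(
      "read_affinity_table: rejected %d of %d row(s); see rejected_records()",
      nrow(rejections), nrow(raw)
    ))
  }
  new_affinity_tbl(records, rejections)
}

new_affinity_tbl <- function(records, rejections = NULL) {
  out <- tibble::as_tibble(records)
  class(out) <- c("affinity_tbl", class(tibble::tibble()))
  attr(out, "rejections") <- rejections %||%
    tibble::tibble(row = integer(), peptide = character(), reason = character())
  out
}

#' Rejected rows of an affinity table
#'
#' @param x An `affinity_tbl` from [read_affinity_table()].
#' @return Tibble with columns `row`, `peptide`, `reason`.
#' @export
rejected_records <- function(x) {
  attr(x, "rejections") %||%
    tibble::tibble(row = integer(), peptide = character(), reason = character())
}

#' Validate a data frame of affinity records
#'
#' Checks the affinity-record invariants on an in-memory data frame (the same
#' checks [read_affinity_table()] applies while parsing) and stops at the
#' first violation.
#'
#' @param records Data frame with columns `allele`, `peptide`, `ic50_nm`,
#'   `inequality`, `kind`.
#' @return The records, invisibly, as an `affinity_tbl`.
#' @export
validate_affinity <- function(records) {
  needed <- c("allele", "peptide", "ic50_nm", "inequality", "kind")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    p <- affinity_row_problem(
      records$peptide[i], records$ic50_nm[i],
      records$inequality[i], records$kind[i]
    )
    if (!is.null(p)) {
      stop(sprintf("invalid affinity record at row %d: %s", i, p), call. = FALSE)
    }
  }
  invisible(new_affinity_tbl(records))
}

#' Write an affinity table in the canonical dialect
#'
#' Serialises records so that reading the file back with
#' [read_affinity_table()] reproduces a row-equivalent table.
#'
#' @param records Affinity records (see [read_affinity_table()]).
#' @param path Output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- data.frame(
    allele = records$allele,
    peptide = records$peptide,
    ic50_nM = records$ic50_nm,
    inequality = names(ineq_codes)[match(records$inequality, ineq_codes)],
    kind = ifelse(records$kind == "quantitative", "quant", "qual")
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter records by peptide length
#'
#' Keeps records whose peptide length lies in `[min_len, max_len]`, preserving
#' order. The benchmark datasets in this field restrict lengths per MHC class
#' (e.g. 8-11 for class I, 15 for class II); the number of removed records is
#' reported via the `n_removed` attribute.
#'
#' @param records Affinity records, or any data frame with a `peptide` column.
#' @param min_len,max_len Inclusive length bounds, `min_len <= max_len`.
#' @return The filtered records with attribute `n_removed`.
#' @export
filter_by_length <- function(records, min_len, max_len) {
  if (min_len > max_len) {
    stop("min_len must not exceed max_len", call. = FALSE)
  }
  len <- nchar(records$peptide)
  keep <- len >= min_len & len <= max_len
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
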