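# Readers/writers for the tab-separated expression, trait and schema files.
# Dialect: UTF-8 TSV, first column = feature id, header row = sample ids.

readMatrixTSV <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop(what, " file must have an id column and >= 1 sample")
  ids <- raw[[1]]
  samples <- colnames(raw)[-1]
  list(ids = ids, samples = samples,
       cells = as.matrix(raw[, -1, drop = FALSE]))
}

#' Read a transcript abundance matrix
#'
#' Reads a tab-separated transcripts x samples table (header row of sample
#' ids, first column of transcript ids) into a validated
#' [ExpressionMatrix-class].  Row order is preserved from the file.
#'
#' @param path path to the TSV file.
#' @return an `ExpressionMatrix`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "tA\t1.5\t2", "tB\t0\t7"), f)
#' readExpression(f)
#' @export
readExpression <- function(path) {
  m <- readMatrixTSV(path, "expression")
  checkUniqueIds(m$ids, "transcript")
  checkUniqueIds(m$samples, "sample")
  vals <- suppressWarnings(array(as.numeric(m$cells), dim = dim(m$cells)))
  bad <- which(is.na(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "invalid abundance value '%s' at transcript '%s', sample '%s' (must be a nonnegative number)",
      m$cells[i, j], m$ids[i], m$samples[j]))
  }
  dimnames(vals) <- list(m$ids, m$samples)
  ExpressionMatrix(vals)
}

#' Write a transcript abundance matrix
#'
#' Inverse of [readExpression()]; values are printed at full precision so a
#' read-back reproduces them bit-exactly.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  writeMatrixTSV(x@values, path, idHeader = "transcript_id")
}

writeMatrixTSV <- function(v, path, idHeader) {
  lines <- c(paste(c(idHeader, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], fmtNum(v[i, ])), collapse = "\t"),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a trait schema
#'
#' A YAML (or JSON) file mapping each trait id to its kind and, for
#' categorical traits, the label-to-code encoding, e.g.
#' \preformatted{
#' FT:
#'   kind: categorical
#'   encoding: {early: 0, late: 1}
#' YP13:
#'   kind: quantitative
#' }
#'
#' @param path path to the schema file.
#' @return a named list with one `list(kind=, encoding=)` entry per trait.
#' @export
readTraitSchema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  schema <- yaml::read_yaml(path)
  for (tr in names(schema)) {
    kind <- schema[[tr]]$kind
    if (is.null(kind) || !kind %in% c("quantitative", "categorical"))
      stop("schema for trait '", tr,
           "' must declare kind 'quantitative' or 'categorical'")
    if (kind == "categorical") {
      enc <- schema[[tr]]$encoding
      if (is.null(enc) || is.null(names(enc)))
        stop("categorical trait '", tr, "' needs a label->code encoding")
      schema[[tr]]$encoding <- unlist(enc)
    }
  }
  schema
}

#' Read a phenotype trait table
#'
#' Reads a traits x samples TSV.  Categorical labels are mapped through the
#' declared encoding (already-encoded numeric codes are also accepted);
#' the `naToken` (default "NA") marks missing observations and is preserved
#' as NA.  An all-NA trait row triggers a warning but is retained.
#'
#' @param path path to the TSV file.
#' @param schema trait-kind declaration as returned by [readTraitSchema()],
#'   or a path to a schema file.  Traits absent from the schema default to
#'   quantitative.
#' @param naToken token marking missing values.
#' @return a [TraitTable-class].
#' @export
readTraits <- function(path, schema = list(), naToken = "NA") {
  if (is.character(schema) && length(schema) == 1)
    schema <- readTraitSchema(schema)
  m <- readMatrixTSV(path, "trait")
  checkUniqueIds(m$ids, "trait")
  checkUniqueIds(m$samples, "sample")
  vals <- matrix(NA_real_, nrow(m$cells), ncol(m$cells),
                 dimnames = list(m$ids, m$samples))
  kind <- setNames(rep("quantitative", length(m$ids)), m$ids)
  encodings <- list()
  for (i in seq_along(m$ids)) {
    tr <- m$ids[i]
    cells <- m$cells[i, ]
    isNA <- cells == naToken | is.na(cells)
    sc <- schema[[tr]]
    if (!is.null(sc) && sc$kind == "categorical") {
      kind[tr] <- "categorical"
      enc <- sc$encoding
      encodings[[tr]] <- enc
      codes <- enc[cells]
      # accept pre-encoded numeric codes as well as labels
      num <- suppressWarnings(as.numeric(cells))
      codes[is.na(codes) & num %in% enc] <- num[is.na(codes) & num %in% enc]
      bad <- !isNA & is.na(codes)
      if (any(bad))
        stop(sprintf(
          "label '%s' of categorical trait '%s' (sample '%s') is not in its declared encoding",
          cells[which(bad)[1]], tr, m$samples[which(bad)[1]]))
      vals[i, !isNA] <- codes[!isNA]
    } else {
      num <- suppressWarnings(as.numeric(cells))
      bad <- !isNA & is.na(num)
      if (any(bad))
        stop(sprintf(
          "invalid value '%s' for quantitative trait '%s' (sample '%s')",
          cells[which(bad)[1]], tr, m$samples[which(bad)[1]]))
      vals[i, !isNA] <- num[!isNA]
    }
    if (all(is.na(vals[i, ])))
      warning("trait '", tr, "' has no non-missing values; row retained")
  }
  TraitTable(vals, kind, encodings)
}

#' Write a phenotype trait table
#'
#' Writes trait codes as TSV (categorical traits keep their numeric codes;
#' the schema file carries the label mapping).
#'
#' @param x a [TraitTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTraits <- function(x, path) {
  stopifnot(is(x, "TraitTable"))
  writeMatrixTSV(x@values, path, idHeader = "trait_id")
}

#' Write a trait schema
#'
#' @param x a [TraitTable-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeTraitSchema <- function(x, path) {
  stopifnot(is(x, "TraitTable"))
  schema <- lapply(featureIds(x), function(tr) {
    if (x@traitKind[[tr]] == "categorical")
      list(kind = "categorical", encoding = as.list(x@encodings[[tr]]))
    else list(kind = "quantitative")
  })
  names(schema) <- featureIds(x)
  yaml::write_yaml(schema, path)
  invisible(path)
}

#' Restrict expression and trait tables to their shared samples
#'
#' Both objects are restricted to the intersection of their sample sets, with
#' columns in identical order (the expression table's order).  The operation
#' is idempotent.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param traits a [TraitTable-class].
#' @return a list with elements `expression`, `traits`, and `dropped` (a list
#'   of the sample ids dropped from each input).
#' @export
alignSamples <- function(expr, traits) {
  stopifnot(is(expr, "ExpressionMatrix"), is(traits, "TraitTable"))
  se <- sampleIds(expr)
  st <- sampleIds(traits)
  shared <- se[se %in% st]
  if (length(shared) == 0)
    stop("expression and trait tables share no samples; cannot align")
  list(expression = ExpressionMatrix(expr@values[, shared, drop = FALSE]),
       traits = TraitTable(traits@values[, shared, drop = FALSE],
                           traits@traitKind, traits@encodings),
       dropped = list(expression = setdiff(se, shared),
                      traits = setdiff(st, shared)))
}
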