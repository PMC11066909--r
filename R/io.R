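#' @importFrom utils read.delim write.table
NULL

# Full-precision, locale-independent number formatting so that
# write -> read -> write round-trips are byte-identical.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read an omics matrix from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row holds sample ids and
#' whose first column holds feature ids. Empty cells and \code{"NA"} are
#' treated as missing. Duplicate feature or sample ids, non-numeric cells and
#' (for methylome data) beta values outside [0, 1] are rejected with a message
#' naming the offender.
#'
#' @param path file path.
#' @param assayKind \code{"proteome"}, \code{"transcriptome"} or
#'   \code{"methylome"}.
#' @param sampleInfo optional per-sample annotation data.frame (see
#'   \code{\link{readSampleAnnotation}}).
#' @return an \linkS4class{OmicsMatrix}.
#' @seealso \code{\link{writeOmicsMatrix}}
#' @export
readOmicsMatrix <- function(path, assayKind, sampleInfo = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("matrix file needs a feature-id column and at least one sample")
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sid <- colnames(raw)[-1L]
  if (anyDuplicated(sid))
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(sid), dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    cell <- raw[[j + 1L]]
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   cell[bad[1L]], fid[bad[1L]], sid[j]))
    vals[, j] <- num
  }
  m <- OmicsMatrix(vals, assayKind, sampleInfo = sampleInfo)
  validObject(m)
  m
}

#' Write an omics matrix to TSV
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param path output file path.
#' @param idColumn name of the feature-id column header.
#' @return invisibly, \code{path}.
#' @export
writeOmicsMatrix <- function(x, path, idColumn = "feature_id") {
  v <- if (is(x, "OmicsMatrix")) assay(x) else as.matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(v)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], .fmtNum(v[i, ])), collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a sample annotation sidecar TSV
#'
#' Fixed columns: \code{sample_id}, \code{entity} (ETMR/ATRT/MB/other),
#' \code{subgroup} (ETANTR/EBL_MEPL/none), \code{batch}, \code{pair_id}
#' (optional microdissection pair), \code{is_reference} (logical). Subgroups
#' other than \code{none} are only valid for ETMR samples; a pair id must
#' occur exactly twice with distinct subgroups.
#'
#' @param path file path.
#' @return a data.frame keyed by \code{sample_id}.
#' @export
readSampleAnnotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("sample_id", "entity", "subgroup", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!"pair_id" %in% colnames(df)) df$pair_id <- NA_character_
  df$pair_id[df$pair_id == ""] <- NA_character_
  df$is_reference <- if ("is_reference" %in% colnames(df)) {
    tolower(df$is_reference) %in% c("true", "t", "1", "yes")
  } else FALSE
  msgs <- .checkSampleInfo(df)
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  rownames(df) <- df$sample_id
  df
}

#' Write a sample annotation sidecar TSV
#'
#' @param annotation data.frame as returned by
#'   \code{\link{readSampleAnnotation}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  df$is_reference <- ifelse(df$is_reference, "true", "false")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one tab-separated line per set with fields set id,
#' description, then one or more member gene symbols. Members are
#' de-duplicated; their order is not significant.
#'
#' @param path file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); expected set id, description and >= 1 member",
                   i, length(fields)))
    id <- fields[[1L]]
    if (id %in% names(sets)) stop("duplicated set id: ", id)
    sets[[id]] <- unique(fields[-(1:2)])
    descs[[id]] <- fields[[2L]]
  }
  GeneSetCollection(sets, names = descs)
}

#' Write gene sets to a GMT file
#'
#' Members are written in sorted order so that round-trips are deterministic.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  ids <- setIds(collection)
  lines <- vapply(ids, function(id)
    paste(c(id, collection@names[[id]], sort(collection@sets[[id]])),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology from an OBO-lite file
#'
#' Honors only \code{[Term]} stanzas and the tags \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and \code{is_obsolete}; obsolete terms and
#' unknown tags are skipped. Edges to terms missing from the file are dropped.
#'
#' @param path file path.
#' @param annotations optional named list of direct gene annotations (term id
#'   to gene symbols), propagated to ancestors on construction.
#' @return an \linkS4class{OntologyDAG}.
#' @export
readOboLite <- function(path, annotations = list()) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); parents <- list()
  cur <- NULL; inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <<- data.frame(
        id = cur$id,
        name = if (is.null(cur$name)) cur$id else cur$name,
        namespace = if (is.null(cur$namespace)) "default" else cur$namespace,
        stringsAsFactors = FALSE)
      parents[[cur$id]] <<- cur$is_a %||% character()
    }
  }
  for (line in lines) {
    line <- sub("!.*$", "", line)
    line <- trimws(line)
    if (line == "[Term]") { flush(); cur <- list(is_a = character()); inTerm <- TRUE; next }
    if (grepl("^\\[", line)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || !nzchar(line)) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[[2L]]; val <- trimws(kv[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s")[[1L]][1L])
    else if (key == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
  }
  flush()
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  OntologyDAG(do.call(rbind, terms), parents, annotations)
}

#' Write an ontology to an OBO-lite file
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeOboLite <- function(dag, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[[i]]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag@terms$name[[i]]),
                 paste0("namespace: ", dag@terms$namespace[[i]]),
                 paste0("is_a: ", sort(dag@parents[[id]]))), con)
  }
  invisible(path)
}

#' Read a CpG probe annotation TSV
#'
#' Columns: \code{cpg_id}, \code{gene}, \code{region} (TSS200 / TSS1500 /
#' UTR5 / body / other), \code{chromosome}, \code{flags}
#' (comma-separated subset of sex_chromosome, snp_at_cpg, cross_reactive;
#' empty for none).
#'
#' @param path file path.
#' @return a data.frame keyed by \code{cpg_id}, with a list column
#'   \code{flags}.
#' @export
readCpgAnnotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("cpg_id", "gene", "region", "chromosome")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("CpG annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cpg_id))
    stop("duplicated cpg_id(s): ",
         paste(unique(df$cpg_id[duplicated(df$cpg_id)]), collapse = ", "))
  bad <- setdiff(unique(df$region), .REGIONS)
  if (length(bad))
    stop("unknown region value(s): ", paste(bad, collapse = ", "))
  flags <- if ("flags" %in% colnames(df)) df$flags else rep("", nrow(df))
  df$flags <- lapply(flags, function(f) {
    f <- setdiff(trimws(strsplit(f, ",", fixed = TRUE)[[1L]]), "")
    bad <- setdiff(f, .PROBE_FLAGS)
    if (length(bad)) stop("unknown probe flag(s): ", paste(bad, collapse = ", "))
    f
  })
  rownames(df) <- df$cpg_id
  df
}

#' Write a CpG probe annotation TSV
#'
#' @param annotation data.frame as returned by
#'   \code{\link{readCpgAnnotation}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCpgAnnotation <- function(annotation, path) {
  df <- as.data.frame(annotation[, c("cpg_id", "gene", "region", "chromosome")])
  df$flags <- vapply(annotation$flags, paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
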