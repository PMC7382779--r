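#' Read a reporter-intensity table from TSV
#'
#' The expected layout is one header row (`id` followed by channel IDs), then
#' one row per molecule. Cells are non-negative numbers; an empty cell encodes
#' a missing value (never `NA` text or 0). Channel metadata is attached from
#' `channels` when supplied, otherwise all channels are read as samples and
#' the bridge must be set later.
#'
#' @param path TSV file path.
#' @param plex_id Plex identifier (defaults to the file name).
#' @param level Quantification level of the table.
#' @param channels Optional channel metadata data frame (see [plex_table()]).
#' @return A [plex_table()] if `channels` is given, otherwise a bare intensity
#'   matrix with molecule rownames.
#' @export
read_intensity_table <- function(path, plex_id = basename(path),
                                 level = "protein", channels = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("format error in '", path, "': empty file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad to header width before checking
  header <- cells[[1L]]
  ncol_exp <- length(header)
  ids <- character(length(cells) - 1L)
  mat <- matrix(NA_real_, length(cells) - 1L, ncol_exp - 1L,
                dimnames = list(NULL, header[-1L]))
  for (i in seq_along(ids)) {
    row <- cells[[i + 1L]]
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    if (length(row) != ncol_exp)
      stop("format error in '", path, "': row ", i + 1L, " has ", length(row),
           " fields, expected ", ncol_exp)
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    bad <- !nzchar(row[-1L])
    if (any(is.na(vals) & !bad))
      stop("format error in '", path, "': row ", i + 1L, " has a non-numeric cell")
    if (any(vals < 0, na.rm = TRUE))
      stop("format error in '", path, "': row ", i + 1L, " has a negative intensity")
    vals[bad] <- NA_real_
    mat[i, ] <- vals
  }
  if (anyDuplicated(ids))
    stop("format error in '", path, "': duplicate molecule ID '",
         ids[duplicated(ids)][1L], "'")
  rownames(mat) <- ids
  if (is.null(channels)) return(mat)
  plex_table(plex_id, level, channels, mat)
}

#' Write a reporter-intensity table as TSV
#'
#' Missing values are written as empty cells so that
#' [read_intensity_table()] round-trips values and missingness losslessly.
#'
#' @param table A [plex_table()] or intensity matrix with molecule rownames.
#' @param path Output file path.
#' @export
write_intensity_table <- function(table, path) {
  mat <- if (inherits(table, "plex_table")) table$intensities else table
  df <- as.data.frame(mat)
  df[] <- lapply(df, function(v) ifelse(is.na(v), "", format(v, digits = 15,
                                                             scientific = FALSE,
                                                             trim = TRUE)))
  df <- cbind(id = rownames(mat), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a log2 ratio matrix as TSV
#'
#' Sample columns are labeled `strain::R<replicate>` (or just the strain name
#' for merged matrices); empty cells encode missing values.
#'
#' @param rm A [ratio_matrix()].
#' @param path File path.
#' @return `read_ratio_matrix` returns a [ratio_matrix()].
#' @export
write_ratio_matrix <- function(rm, path) {
  write_intensity_table(rm$values, path)
}

#' @rdname write_ratio_matrix
#' @param level Level recorded on the matrix being read.
#' @export
read_ratio_matrix <- function(path, level = "protein") {
  mat <- abs_safe_read(path)
  lab <- colnames(mat)
  has_rep <- grepl("::R\\d+$", lab)
  samples <- data.frame(
    strain = sub("::R\\d+$", "", lab),
    replicate = ifelse(has_rep, as.integer(sub("^.*::R", "", lab)), NA_integer_),
    stringsAsFactors = FALSE)
  ratio_matrix(level, mat, samples)
}

abs_safe_read <- function(path) {
  # ratio matrices may be negative; reuse the intensity reader minus the
  # non-negativity check by shifting through a raw parse
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  ncol_exp <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(body, `[`, "", 1L)
  mat <- matrix(NA_real_, length(body), ncol_exp - 1L,
                dimnames = list(ids, header[-1L]))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    vals <- suppressWarnings(as.numeric(row[-1L]))
    vals[!nzchar(row[-1L])] <- NA_real_
    mat[i, ] <- vals
  }
  mat
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term <tab> description <tab> gene1 <tab> gene2 ...`. Duplicate members
#' within a term are collapsed.
#'
#' @param path GMT file path.
#' @param name Database label (defaults to the file name).
#' @param kind Database kind, see [annotation_db()].
#' @return An [annotation_db()].
#' @export
read_gmt <- function(path, name = basename(path), kind = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("GMT file '", path, "' is empty")
    return(annotation_db(name, kind, sets = stats::setNames(list(), character())))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short))
    stop("format error in '", path, "': line ", short[1L],
         " has fewer than 3 fields")
  sets <- lapply(cells, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(cells, `[`, "", 1L)
  annotation_db(name, kind, sets = sets)
}

#' Write a GMT gene-set file
#' @param db An [annotation_db()] with term sets.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(db$kind != "interaction")
  lines <- vapply(names(db$sets), function(tm)
    paste(c(tm, db$name, db$sets[[tm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pairwise-relationship table (two-column TSV)
#'
#' Carrier for interaction databases (e.g. curated protein-protein
#' interactions). Pairs are unordered and deduplicated.
#'
#' @param path TSV with at least two columns (header optional via `header`).
#' @param name Database label.
#' @param header Whether the file has a header line.
#' @return An [annotation_db()] of kind `"interaction"`.
#' @export
read_pair_db <- function(path, name = basename(path), header = TRUE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  annotation_db(name, "interaction", pairs = df[, 1:2])
}

#' Export a network edge or call list
#'
#' `dialect = "sif"` writes Cytoscape-compatible SIF lines with interaction
#' labels `pos`/`neg` (correlation edges, from the `sign` column) or
#' `up`/`down` (regulation calls, from the `direction` column).
#' `dialect = "tsv"` writes all columns, always with a header. Rows are
#' ordered by the first two node columns for stable output.
#'
#' @param edges Data frame of edges; first two columns are the node IDs.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sif"`.
#' @export
write_network <- function(edges, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  edges <- as.data.frame(edges)
  if (nrow(edges))
    edges <- edges[order(edges[[1L]], edges[[2L]]), , drop = FALSE]
  if (dialect == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lab <- if ("sign" %in% names(edges)) as.character(edges$sign)
           else if ("direction" %in% names(edges)) as.character(edges$direction)
           else rep("link", nrow(edges))
    writeLines(paste(edges[[1L]], lab, edges[[2L]]), path)
  }
  invisible(path)
}

#' Write / read a plex design file
#'
#' The design is stored as structured key-value text (YAML): one entry per
#' plex listing its channels with strain, replicate, bridge flag and growth
#' batch.
#'
#' @param design A [build_design()] data frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  plexes <- lapply(split(seq_len(nrow(design)), design$plex), function(i) {
    pd <- design[i, , drop = FALSE]
    list(plex = pd$plex[1L],
         channels = lapply(seq_len(nrow(pd)), function(j)
           list(channel = pd$channel[j], strain = pd$strain[j],
                replicate = pd$replicate[j], bridge = pd$is_bridge[j],
                batch = if (is.na(pd$batch[j])) NULL else pd$batch[j])))
  })
  yaml::write_yaml(list(plexes = unname(plexes)), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(y$plexes, function(p)
    do.call(rbind, lapply(p$channels, function(ch)
      data.frame(plex = p$plex, channel = as.character(ch$channel),
                 strain = ch$strain, replicate = ch$replicate,
                 is_bridge = isTRUE(ch$bridge),
                 batch = if (is.null(ch$batch)) NA_integer_ else ch$batch,
                 stringsAsFactors = FALSE)))))
  rownames(rows) <- NULL
  class(rows) <- c("plex_design", "data.frame")
  rows
}

#' Parse and format phosphosite identifiers
#'
#' Sites are keyed as `PROTEIN_pS123`, multiply-phosphorylated combinations
#' as `PROTEIN_pS123_pT130`. Residues are S/T/Y; positions are 1-based on the
#' protein sequence and strictly increasing.
#'
#' @param id A site identifier string.
#' @return `parse_site_id`: list with `protein`, `residues`, `positions`.
#' @export
parse_site_id <- function(id) {
  parts <- strsplit(id, "_p", fixed = TRUE)[[1L]]
  if (length(parts) < 2L)
    stop("malformed phosphosite ID '", id, "'")
  protein <- parts[1L]
  res <- substr(parts[-1L], 1L, 1L)
  pos <- suppressWarnings(as.integer(substring(parts[-1L], 2L)))
  if (any(!res %in% c("S", "T", "Y")) || any(is.na(pos)) || any(pos < 1L))
    stop("malformed phosphosite ID '", id, "'")
  if (length(pos) > 1L && any(diff(pos) <= 0L))
    stop("phosphosite ID '", id, "': positions must be strictly increasing")
  list(protein = protein, residues = res, positions = pos)
}

#' @rdname parse_site_id
#' @param protein Protein/gene identifier.
#' @param residues Character vector of residues (S/T/Y).
#' @param positions Integer vector of 1-based positions, strictly increasing.
#' @export
format_site_id <- function(protein, residues, positions) {
  stopifnot(length(residues) == length(positions), length(positions) >= 1L,
            all(residues %in% c("S", "T", "Y")),
            all(positions >= 1L), !is.unsorted(positions, strictly = TRUE))
  paste0(protein, paste0("_p", residues, positions, collapse = ""))
}
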