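#' Reporter-intensity table for a single multiplexed run
#'
#' Container for the molecules-by-channels reporter intensity matrix of one
#' isobaric plex, together with the channel metadata (strain, replicate,
#' bridge flag). Exactly one channel per plex is the wild-type bridge.
#'
#' @param plex_id Character scalar identifying the plex.
#' @param level One of `"peptide"`, `"protein"`, `"phosphosite"`.
#' @param channels Data frame with columns `channel`, `strain`, `replicate`,
#'   `is_bridge` (one row per channel, exactly one bridge).
#' @param intensities Numeric matrix, molecules in rows (rownames are molecule
#'   IDs), channels in columns, non-negative, `NA` for missing.
#' @return An object of class `plex_table`.
#' @export
plex_table <- function(plex_id, level, channels, intensities) {
  level <- match.arg(level, c("peptide", "protein", "phosphosite"))
  stopifnot(is.data.frame(channels),
            all(c("channel", "strain", "replicate", "is_bridge") %in% names(channels)),
            is.matrix(intensities))
  if (sum(channels$is_bridge) != 1L)
    stop("plex '", plex_id, "': exactly one bridge channel required, found ",
         sum(channels$is_bridge))
  if (ncol(intensities) != nrow(channels))
    stop("plex '", plex_id, "': intensity columns (", ncol(intensities),
         ") do not match channel metadata rows (", nrow(channels), ")")
  if (is.null(rownames(intensities)))
    stop("plex '", plex_id, "': intensity matrix must carry molecule IDs as rownames")
  if (anyDuplicated(rownames(intensities)))
    stop("plex '", plex_id, "': duplicate molecule ID '",
         rownames(intensities)[duplicated(rownames(intensities))][1L], "'")
  if (any(intensities < 0, na.rm = TRUE))
    stop("plex '", plex_id, "': negative intensities are not allowed")
  colnames(intensities) <- channels$channel
  structure(list(plex_id = plex_id, level = level,
                 channels = channels, intensities = intensities),
            class = "plex_table")
}

#' @export
print.plex_table <- function(x, ...) {
  cat(sprintf("<plex_table> %s  level=%s  %d molecules x %d channels (bridge: %s)\n",
              x$plex_id, x$level, nrow(x$intensities), ncol(x$intensities),
              x$channels$channel[x$channels$is_bridge]))
  invisible(x)
}

#' Log2 ratio matrix relative to the wild-type bridge
#'
#' Molecules-by-samples matrix of log2 ratios to the bridge channel. Sample
#' columns are identified by (strain, replicate); a merged (strain-level)
#' matrix carries `replicate = NA`.
#'
#' @param level `"protein"` or `"phosphosite"` (or `"peptide"`).
#' @param values Numeric matrix with molecule rownames; `NA` for missing.
#' @param samples Data frame with columns `strain`, `replicate`, one row per
#'   column of `values`.
#' @param normalized Optional logical matrix (same shape as `values`) flagging
#'   phosphosite entries that were normalized by their cognate protein ratio.
#' @return An object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(level, values, samples, normalized = NULL) {
  stopifnot(is.matrix(values), is.data.frame(samples),
            all(c("strain", "replicate") %in% names(samples)),
            nrow(samples) == ncol(values))
  if (any(is.infinite(values)))
    stop("ratio_matrix values must be finite or missing")
  key <- paste(samples$strain, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (strain, replicate) columns: ",
         samples$strain[duplicated(key)][1L])
  colnames(values) <- sample_labels(samples)
  structure(list(level = level, values = values, samples = samples,
                 normalized = normalized),
            class = "ratio_matrix")
}

sample_labels <- function(samples) {
  ifelse(is.na(samples$replicate), samples$strain,
         paste0(samples$strain, "::R", samples$replicate))
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> level=%s  %d molecules x %d samples (%d strains), %.1f%% missing\n",
              x$level, nrow(x$values), ncol(x$values),
              length(unique(x$samples$strain)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

#' Gene-set / relationship annotation database
#'
#' Term-membership databases (pathway, complex, cellular component, molecular
#' function) hold a named list of gene-ID sets; interaction databases hold a
#' deduplicated table of unordered gene pairs.
#'
#' @param name Database label.
#' @param kind One of `"pathway"`, `"complex"`, `"cellular_component"`,
#'   `"molecular_function"`, `"interaction"`.
#' @param sets Named list of character vectors (ignored for interactions).
#' @param pairs Two-column data frame of gene pairs (interaction kind only).
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(name, kind, sets = NULL, pairs = NULL) {
  kind <- match.arg(kind, c("pathway", "complex", "cellular_component",
                            "molecular_function", "interaction"))
  if (kind == "interaction") {
    stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
    a <- pmin(as.character(pairs[[1L]]), as.character(pairs[[2L]]))
    b <- pmax(as.character(pairs[[1L]]), as.character(pairs[[2L]]))
    keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
    pairs <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
    sets <- NULL
  } else {
    stopifnot(is.list(sets))
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (any(lengths(sets) == 0L)) stop("annotation_db '", name, "': empty term")
    if (any(!nzchar(unlist(sets)))) stop("annotation_db '", name, "': empty gene ID")
    pairs <- NULL
  }
  structure(list(name = name, kind = kind, sets = sets, pairs = pairs),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  if (x$kind == "interaction")
    cat(sprintf("<annotation_db> %s (interaction): %d pairs\n", x$name, nrow(x$pairs)))
  else
    cat(sprintf("<annotation_db> %s (%s): %d terms, %d genes\n", x$name, x$kind,
                length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}
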