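#' Construct a multi-organ circadian expression atlas
#'
#' The atlas is the package's central container: a 3-way array of non-negative
#' FPKM-like expression values indexed by (gene, organ, Zeitgeber time), with
#' equally spaced time points on a half-open \[0, period) circle. One value per
#' (gene, organ, ZT) — one animal per time point, as in body-wide circadian
#' atlases.
#'
#' @param values numeric array gene x organ x time, non-negative, no NA
#'   (unless `allow_na = TRUE`, used internally by readers before imputation).
#' @param gene_ids,organ_ids character identifiers (unique, ordered).
#' @param zt_times numeric hours within the cycle, strictly increasing,
#'   equally spaced, all in \[0, period_hours).
#' @param period_hours cycle length (default 24).
#' @param allow_na allow missing entries (flagged, not silently zero).
#' @return an object of class `ExpressionAtlas`.
#' @export
expression_atlas <- function(values, gene_ids, organ_ids, zt_times,
                             period_hours = 24, allow_na = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  gene_ids <- as.character(gene_ids)
  organ_ids <- as.character(organ_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(organ_ids)) stop("duplicate organ identifiers")
  if (dim(values)[1] != length(gene_ids) ||
      dim(values)[2] != length(organ_ids) ||
      dim(values)[3] != length(zt_times))
    stop("values dimensions do not match gene/organ/time identifiers")
  if (length(zt_times) >= 2) {
    d <- diff(zt_times)
    if (any(d <= 0)) stop("zt_times must be strictly increasing")
    if (max(d) - min(d) > 1e-8) stop("zt_times must be equally spaced")
  }
  if (any(zt_times < 0 | zt_times >= period_hours))
    stop("zt_times must lie in [0, period_hours)")
  if (!allow_na && anyNA(values)) stop("missing expression values")
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression at gene '%s', organ '%s', ZT%02g",
                 gene_ids[bad[1]], organ_ids[bad[2]], zt_times[bad[3]]))
  }
  dimnames(values) <- list(gene_ids, organ_ids, paste0("ZT", zt_times))
  structure(list(values = values, gene_ids = gene_ids, organ_ids = organ_ids,
                 zt_times = as.numeric(zt_times),
                 period_hours = period_hours),
            class = "ExpressionAtlas")
}

#' @export
print.ExpressionAtlas <- function(x, ...) {
  cat(sprintf("ExpressionAtlas: %d genes x %d organs x %d time points (ZT %s; period %g h)\n",
              length(x$gene_ids), length(x$organ_ids), length(x$zt_times),
              paste(x$zt_times, collapse = ","), x$period_hours))
  invisible(x)
}

#' Subset an atlas by genes and/or organs
#' @param atlas an `ExpressionAtlas`.
#' @param genes,organs identifiers (or indices) to keep; NULL keeps all.
#' @return an `ExpressionAtlas`.
#' @export
subset_atlas <- function(atlas, genes = NULL, organs = NULL) {
  g <- if (is.null(genes)) atlas$gene_ids else genes
  o <- if (is.null(organs)) atlas$organ_ids else organs
  if (is.numeric(g)) g <- atlas$gene_ids[g]
  if (is.numeric(o)) o <- atlas$organ_ids[o]
  stopifnot(all(g %in% atlas$gene_ids), all(o %in% atlas$organ_ids))
  expression_atlas(atlas$values[g, o, , drop = FALSE], g, o,
                   atlas$zt_times, atlas$period_hours)
}

# Default wide-TSV layout: columns named <organ><sep>ZT<xx>.
default_layout <- function() list(gene_column = "gene", sep = "_", zt_prefix = "ZT")

#' Read a wide-TSV expression atlas
#'
#' One gene-identifier column plus one column per (organ, ZT) sample, named
#' `<organ>_ZT<hh>` by default (configurable through a small layout
#' descriptor, optionally loaded from YAML).
#'
#' @param path TSV file path.
#' @param layout list with `gene_column`, `sep`, `zt_prefix`; or a path to a
#'   YAML file with those fields.
#' @param period_hours cycle length.
#' @param impute_missing impute NA entries with the per-gene-per-organ median
#'   (logged via the `n_imputed` attribute); default FALSE = error on NA.
#' @return an `ExpressionAtlas`.
#' @export
read_atlas <- function(path, layout = default_layout(), period_hours = 24,
                       impute_missing = FALSE) {
  if (is.character(layout) && length(layout) == 1L)
    layout <- utils::modifyList(default_layout(), yaml::read_yaml(layout))
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e)))
  if (!layout$gene_column %in% names(tab))
    stop("format error: missing gene column '", layout$gene_column, "'")
  gene_ids <- as.character(tab[[layout$gene_column]])
  if (anyDuplicated(gene_ids))
    stop("format error: duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  samp_cols <- setdiff(names(tab), layout$gene_column)
  pat <- paste0("^(.+)", layout$sep, layout$zt_prefix, "([0-9]+(\\.[0-9]+)?)$")
  ok <- grepl(pat, samp_cols)
  if (any(!ok))
    stop("format error: unparseable sample columns: ",
         paste(samp_cols[!ok], collapse = ", "))
  organ <- sub(pat, "\\1", samp_cols)
  zt <- as.numeric(sub(pat, "\\2", samp_cols))
  organ_ids <- unique(organ)
  zt_times <- sort(unique(zt))
  mat <- as.matrix(tab[, samp_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[samp_cols], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[samp_cols[bad]]]))))[1]
    stop(sprintf("format error: non-numeric expression in column '%s', row %d",
                 samp_cols[bad], badrow))
  }
  arr <- array(NA_real_, dim = c(length(gene_ids), length(organ_ids),
                                 length(zt_times)))
  for (j in seq_along(samp_cols)) {
    oi <- match(organ[j], organ_ids)
    ti <- match(zt[j], zt_times)
    arr[, oi, ti] <- mat[, j]
  }
  n_imputed <- 0L
  if (anyNA(arr)) {
    if (!impute_missing)
      stop("missing expression values; rerun with impute_missing = TRUE ",
           "to impute per-gene-per-organ medians")
    for (gi in seq_along(gene_ids)) for (oi in seq_along(organ_ids)) {
      v <- arr[gi, oi, ]
      if (anyNA(v)) {
        arr[gi, oi, is.na(v)] <- stats::median(v, na.rm = TRUE)
        n_imputed <- n_imputed + sum(is.na(v))
      }
    }
  }
  atlas <- expression_atlas(arr, gene_ids, organ_ids, zt_times, period_hours)
  attr(atlas, "n_imputed") <- n_imputed
  atlas
}

#' Write an atlas as a wide TSV (round-trips with [read_atlas()])
#' @param atlas an `ExpressionAtlas`.
#' @param path output path.
#' @param layout layout descriptor, as in [read_atlas()].
#' @export
write_atlas <- function(atlas, path, layout = default_layout()) {
  cols <- list()
  cols[[layout$gene_column]] <- atlas$gene_ids
  for (oi in seq_along(atlas$organ_ids)) for (ti in seq_along(atlas$zt_times)) {
    nm <- paste0(atlas$organ_ids[oi], layout$sep, layout$zt_prefix,
                 formatC(atlas$zt_times[ti], width = 2, flag = "0"))
    cols[[nm]] <- atlas$values[, oi, ti]
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter to expressed genes
#'
#' Per organ, a gene counts as expressed when its value exceeds `threshold` at
#' at least half of the time points. The per-organ verdicts combine via
#' `organ_rule`: `"all"` (default; gene must pass in every organ, so stacked
#' series have no organ-specific gaps) or `"any"` (sensitivity analysis).
#'
#' @param atlas an `ExpressionAtlas`.
#' @param organ_rule `"all"` or `"any"`.
#' @param threshold strict expression threshold (value > threshold).
#' @return the filtered `ExpressionAtlas`; the per-gene audit table (gene,
#'   n_organs_expressed, retained) is attached as attribute `"audit"`.
#' @export
filter_expressed <- function(atlas, organ_rule = c("all", "any"),
                             threshold = 0) {
  organ_rule <- match.arg(organ_rule)
  nt <- length(atlas$zt_times)
  # genes x organs matrix of "expressed in this organ"
  expressed <- apply(atlas$values > threshold, c(1, 2), sum) >= nt / 2
  n_org <- rowSums(expressed)
  keep <- if (organ_rule == "all") n_org == length(atlas$organ_ids)
          else n_org >= 1L
  if (!any(keep)) stop("no genes pass the expression filter")
  out <- subset_atlas(atlas, genes = atlas$gene_ids[keep])
  attr(out, "audit") <- data.frame(gene = atlas$gene_ids,
                                   n_organs_expressed = n_org,
                                   retained = keep, row.names = NULL)
  out
}

#' Standardize each gene x organ time series (location/scale)
#'
#' Each series is centred and scaled to population sd 1; constant series are
#' set to all-zero and flagged. Relative temporal shape (and hence within-organ
#' Spearman correlations between genes) is preserved. Idempotent.
#'
#' @param atlas an `ExpressionAtlas`.
#' @return a list-like `ExpressionAtlas`-shaped object of class
#'   `StandardizedAtlas` (values may be negative, so it is no longer an
#'   expression atlas); fields match `ExpressionAtlas` plus `degenerate`,
#'   a genes x organs logical matrix flagging sd-zero series.
#' @export
standardize_per_organ <- function(atlas) {
  v <- atlas$values
  m <- apply(v, c(1, 2), mean)
  s <- apply(v, c(1, 2), pop_sd)
  degen <- s == 0
  s[degen] <- 1
  out <- sweep(sweep(v, c(1, 2), m, "-"), c(1, 2), s, "/")
  out[rep(degen, times = dim(v)[3])] <- 0
  dimnames(out) <- dimnames(v)
  structure(list(values = out, gene_ids = atlas$gene_ids,
                 organ_ids = atlas$organ_ids, zt_times = atlas$zt_times,
                 period_hours = atlas$period_hours, degenerate = degen),
            class = "StandardizedAtlas")
}

#' Classify a Zeitgeber time as day or night
#'
#' Day is the half-open window \[day_start, day_end); defaults \[0, 12) put
#' ZT06 (noon) in the day and ZT12 onward (including ZT18, midnight) in the
#' night.
#'
#' @param zt numeric ZT hours in \[0, period).
#' @param day_start,day_end day window bounds.
#' @param period cycle length.
#' @return character vector `"day"`/`"night"`.
#' @export
assign_day_night <- function(zt, day_start = 0, day_end = 12, period = 24) {
  if (any(zt < 0 | zt >= period)) stop("zt out of [0, period)")
  ifelse(zt >= day_start & zt < day_end, "day", "night")
}

#' Read gene sets
#'
#' Either one identifier per line (`#` comments allowed) giving a single set,
#' or a two-column TSV (set_label, gene) giving several. Duplicates are removed
#' on load; empty sets are an error.
#'
#' @param path file path.
#' @param label label for single-set files (default: file base name).
#' @return named list of character vectors (class `GeneSetList`).
#' @export
read_gene_sets <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty gene-set file: ", path)
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) != 2)) stop("format error: expected 2 columns")
    lab <- vapply(parts, `[`, character(1), 1)
    gene <- vapply(parts, `[`, character(1), 2)
    if (lab[1] %in% c("set_label", "set", "label")) { # header row
      gene <- gene[-1]; lab <- lab[-1]
    }
    sets <- lapply(split(gene, lab), unique)
  } else {
    if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(unique(lines)), label)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set after de-duplication")
  structure(sets, class = "GeneSetList")
}

#' Read an undirected edge list (two-column TSV, optional header)
#'
#' Self-loops are dropped; duplicate edges (in either orientation) collapse.
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to` (class kept plain).
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2) stop("format error: expected 2 columns")
  tab <- tab[, 1:2]
  names(tab) <- c("from", "to")
  if (tolower(tab$from[1]) %in% c("from", "gene1", "a", "source"))
    tab <- tab[-1, , drop = FALSE]
  tab$from <- as.character(tab$from); tab$to <- as.character(tab$to)
  canonical_edges(tab)
}

# Canonicalize an edge data.frame: order within pair, drop self-loops and
# duplicates.
canonical_edges <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- a != b
  df <- unique(data.frame(from = a[keep], to = b[keep],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Write an edge list as two-column TSV
#' @param edges data.frame with columns from, to.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
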