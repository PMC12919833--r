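#' Genomic interval (0-based, half-open)
#'
#' Lightweight interval record used throughout the package. Coordinates are
#' 0-based half-open (BED/BAM native): `start` is the first base, `end` is one
#' past the last. Human-readable printing echoes 1-based inclusive
#' coordinates, but all arithmetic is done on the 0-based representation.
#'
#' @param chrom Chromosome / contig name (non-empty string).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr16", 75204400, 75205700)
#' interval_length(gi)  # 1300
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start/end must be single non-missing numbers")
  if (start < 0) stop("start must be >= 0")
  if (!(start < end)) stop("invalid interval: start (", start, ") must be < end (", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  # 1-based inclusive echo for humans; internal storage stays 0-based
  cat(sprintf("%s:%d-%d (0-based half-open; %d bp)\n",
              x$chrom, as.integer(x$start) + 1L, as.integer(x$end),
              as.integer(interval_length(x))))
  invisible(x)
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' Containment / overlap helpers for genomic intervals
#'
#' @param outer,inner,a,b `genomic_interval` objects.
#' @return `interval_contains()`: TRUE when `inner` lies wholly inside
#'   `outer` (same chromosome). `interval_overlap_width()`: number of
#'   shared bases (0 when disjoint or on different chromosomes).
#' @keywords internal
#' @export
interval_contains <- function(outer, inner) {
  identical(outer$chrom, inner$chrom) &&
    inner$start >= outer$start && inner$end <= outer$end
}

#' @rdname interval_contains
#' @export
interval_overlap_width <- function(a, b) {
  if (!identical(a$chrom, b$chrom)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Deletion locus definition
#'
#' Bundles the deleted interval, the evidence-collection window that contains
#' it, and any confounder regions (intervals where inverted-orientation read
#' pairs are artifacts of a paralogous inversion and count only toward total
#' coverage, never toward the deletion allele).
#'
#' @param name Locus identifier, e.g. `"CTRB2ex6"`.
#' @param deleted `genomic_interval`: the deleted sequence.
#' @param window `genomic_interval` containing `deleted`: the region over
#'   which alignment evidence is collected.
#' @param confounders List of `genomic_interval` confounder regions.
#' @param reference_build Reference genome build label.
#' @return An object of class `deletion_locus`.
#' @export
deletion_locus <- function(name, deleted, window, confounders = list(),
                           reference_build = "GRCh38") {
  stopifnot(inherits(deleted, "genomic_interval"),
            inherits(window, "genomic_interval"))
  if (!is.character(name) || !nzchar(name)) stop("locus name must be non-empty")
  if (!interval_contains(window, deleted))
    stop("validation error: deleted interval must lie within the window")
  if (!all(vapply(confounders, inherits, logical(1), "genomic_interval")))
    stop("confounders must be a list of genomic_interval objects")
  structure(list(name = name, deleted = deleted, window = window,
                 confounders = confounders, reference_build = reference_build),
            class = "deletion_locus")
}

#' @export
print.deletion_locus <- function(x, ...) {
  cat("Deletion locus:", x$name, "(", x$reference_build, ")\n")
  cat("  window : "); print(x$window)
  cat("  deleted: "); print(x$deleted)
  if (length(x$confounders))
    for (cf in x$confounders) { cat("  confounder: "); print(cf) }
  invisible(x)
}

#' Bundled CTRB2 exon 6 deletion locus
#'
#' The default locus: a 584-bp germline deletion overlapping exon 6 of CTRB2,
#' with evidence collected over chr16:75204400-75205700 (GRCh38, 0-based
#' half-open; 1300 bp). The published description fixes the window and the
#' deletion length but not the exact breakpoints, so the bundled deleted
#' interval is centered in the window and documented as approximate;
#' breakpoints are configuration, not algorithm. The confounder interval
#' stands in for the adjacent CTRB1 paralog region whose germline inversion
#' produces large-insert-looking read pairs.
#'
#' @return A `deletion_locus`.
#' @export
default_locus <- function() {
  win <- genomic_interval("chr16", 75204400, 75205700)
  pad <- (interval_length(win) - 584) / 2  # 358 bp each side
  del <- genomic_interval("chr16", win$start + pad, win$start + pad + 584)
  deletion_locus(
    name = "CTRB2ex6",
    deleted = del,
    window = win,
    confounders = list(genomic_interval("chr16", 75204400, 75204700)),
    reference_build = "GRCh38"
  )
}

#' Parse a deletion locus from JSON or a BED line
#'
#' JSON configs carry a `schema_version` key plus `name`, `reference_build`,
#' and `deleted`/`window`/`confounders` interval objects (`chrom`, `start`,
#' `end`, 0-based half-open). A single BED line (`chrom<TAB>start<TAB>end[<TAB>name]`,
#' 0-based half-open) defines the deleted interval; the window is the deleted
#' interval padded by `window_padding` on each side, clipped at 0.
#'
#' @param config_text A JSON string/file path, or one BED line.
#' @param window_padding Padding (bp) used when parsing a BED line.
#' @return A validated `deletion_locus`.
#' @examples
#' parse_locus("chr1\t100\t684\ttoyDel", window_padding = 500)
#' @export
parse_locus <- function(config_text, window_padding = 500) {
  stopifnot(is.character(config_text), length(config_text) == 1L)
  txt <- config_text
  if (!grepl("[{\t]", txt) && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) return(parse_locus_json(txt))
  parse_locus_bed(txt, window_padding)
}

parse_locus_json <- function(txt) {
  cfg <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("parse error: invalid JSON locus config: ",
                                           conditionMessage(e)))
  as_gi <- function(obj, field) {
    for (k in c("chrom", "start", "end"))
      if (is.null(obj[[k]])) stop("parse error in field '", field, "': missing '", k, "'")
    tryCatch(genomic_interval(obj$chrom, obj$start, obj$end),
             error = function(e) stop("parse error in field '", field, "': ",
                                      conditionMessage(e)))
  }
  if (is.null(cfg$deleted)) stop("parse error: missing field 'deleted'")
  if (is.null(cfg$window)) stop("parse error: missing field 'window'")
  deletion_locus(
    name = if (is.null(cfg$name)) "locus" else cfg$name,
    deleted = as_gi(cfg$deleted, "deleted"),
    window = as_gi(cfg$window, "window"),
    confounders = lapply(seq_along(cfg$confounders), function(i)
      as_gi(cfg$confounders[[i]], paste0("confounders[", i, "]"))),
    reference_build = if (is.null(cfg$reference_build)) "unknown" else cfg$reference_build
  )
}

parse_locus_bed <- function(line, window_padding) {
  f <- strsplit(trimws(line), "\t", fixed = TRUE)[[1]]
  if (length(f) < 3L) stop("parse error: BED line needs >= 3 fields (chrom, start, end)")
  start <- suppressWarnings(as.numeric(f[2]))
  end <- suppressWarnings(as.numeric(f[3]))
  if (is.na(start)) stop("parse error in field 'start': not a number: ", f[2])
  if (is.na(end)) stop("parse error in field 'end': not a number: ", f[3])
  del <- genomic_interval(f[1], start, end)
  win <- genomic_interval(f[1], max(0, start - window_padding), end + window_padding)
  deletion_locus(name = if (length(f) >= 4L) f[4] else "locus",
                 deleted = del, window = win, reference_build = "unknown")
}

#' Serialize a deletion locus to JSON
#'
#' Inverse of [parse_locus()] for JSON configs: `parse_locus(serialize_locus(x))`
#' reproduces `x` for any valid locus.
#'
#' @param locus A `deletion_locus`.
#' @return A JSON string (schema_version 1).
#' @export
serialize_locus <- function(locus) {
  stopifnot(inherits(locus, "deletion_locus"))
  gi_list <- function(x) list(chrom = x$chrom, start = x$start, end = x$end)
  jsonlite::toJSON(list(
    schema_version = 1,
    name = locus$name,
    reference_build = locus$reference_build,
    deleted = gi_list(locus$deleted),
    window = gi_list(locus$window),
    confounders = lapply(locus$confounders, gi_list)
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# GRanges view (1-based) of the evidence window, for indexed BAM access.
locus_window_granges <- function(locus) {
  GenomicRanges::GRanges(locus$window$chrom,
                         IRanges::IRanges(locus$window$start + 1L, locus$window$end))
}
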