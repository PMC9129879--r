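#' Four-channel sequencing trace
#'
#' A `trace_signal` bundles the raw four-channel fluorescence intensities of a
#' Sanger-style chromatogram with its called bases and the scan position of
#' each call. All coordinates are 0-based: scan positions run over
#' `0 .. L - 1` and `peak_pos` indexes into that range.
#'
#' @param intensities Data frame with columns `pos` (0-based scan index,
#'   consecutive from 0) and one column per channel `A`, `C`, `G`, `T` holding
#'   nonnegative fluorescence values (arbitrary units).
#' @param basecalls Data frame with columns `index` (0-based basecall index,
#'   consecutive from 0), `base` (one of A, C, G, T, N) and `peak_pos`
#'   (0-based scan index of the call's peak, strictly increasing).
#'
#' @return An object of class `trace_signal` with elements `intensities`
#'   (tibble) and `basecalls` (tibble).
#' @seealso [read_trace()], [write_trace()], [simulate_trace()]
#' @export
#' @examples
#' tr <- simulate_trace("ACGTACGT", snp_index = 4, fraction_primary = 0.6)
#' tr
trace_signal <- function(intensities, basecalls) {
  check_columns(intensities, c("pos", "A", "C", "G", "T"), "intensities")
  check_columns(basecalls, c("index", "base", "peak_pos"), "basecalls")
  x <- structure(
    list(
      intensities = as_tibble(intensities),
      basecalls = as_tibble(basecalls)
    ),
    class = "trace_signal"
  )
  validate_trace_signal(x)
}

trace_channels <- c("A", "C", "G", "T")

#' Validate a trace_signal's invariants
#'
#' Checks channel lengths, nonnegativity of intensities, and strict
#' monotonicity of peak positions. Called by the constructor and by
#' [write_trace()]; errors name the offending record.
#'
#' @param x A `trace_signal`.
#' @return `x`, invisibly classed, if valid; otherwise an error of class
#'   `epimem_format_error`.
#' @export
validate_trace_signal <- function(x) {
  ints <- x$intensities
  bc <- x$basecalls
  L <- nrow(ints)
  if (L == 0) {
    abort("trace has zero scan positions", class = "epimem_format_error")
  }
  for (ch in trace_channels) {
    v <- ints[[ch]]
    if (anyNA(v)) {
      abort(
        sprintf(
          "channel %s has missing values (first at pos %d): channel lengths unequal or row malformed",
          ch, ints$pos[which(is.na(v))[1]]
        ),
        class = "epimem_format_error"
      )
    }
    if (any(v < 0)) {
      abort(
        sprintf(
          "channel %s has negative intensity at pos %d",
          ch, ints$pos[which(v < 0)[1]]
        ),
        class = "epimem_format_error"
      )
    }
  }
  if (!identical(as.integer(ints$pos), 0:(L - 1L))) {
    abort("`pos` must run consecutively from 0", class = "epimem_format_error")
  }
  if (nrow(bc) == 0) {
    abort("trace has no basecalls", class = "epimem_format_error")
  }
  if (anyNA(bc$peak_pos) || anyNA(bc$base)) {
    abort("basecall block has missing fields", class = "epimem_format_error")
  }
  if (!all(bc$base %in% c(trace_channels, "N"))) {
    bad <- bc$index[which(!bc$base %in% c(trace_channels, "N"))[1]]
    abort(sprintf("invalid called base at basecall %d", bad),
      class = "epimem_format_error"
    )
  }
  pp <- bc$peak_pos
  if (any(pp < 0) || any(pp >= L)) {
    bad <- bc$index[which(pp < 0 | pp >= L)[1]]
    abort(sprintf("peak position out of range at basecall %d", bad),
      class = "epimem_format_error"
    )
  }
  if (nrow(bc) > 1 && any(diff(pp) <= 0)) {
    bad <- bc$index[which(diff(pp) <= 0)[1] + 1L]
    abort(
      sprintf("peak positions not strictly increasing at basecall %d", bad),
      class = "epimem_format_error"
    )
  }
  if (!identical(as.integer(bc$index), 0:(nrow(bc) - 1L))) {
    abort("basecall `index` must run consecutively from 0",
      class = "epimem_format_error"
    )
  }
  invisible(x)
}

#' @export
print.trace_signal <- function(x, ...) {
  cat(sprintf(
    "<trace_signal> %d scans x 4 channels, %d called bases\n",
    nrow(x$intensities), nrow(x$basecalls)
  ))
  cat(" called: ", paste(x$basecalls$base, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Number of scan positions in a trace
#' @param trace A `trace_signal`.
#' @return Integer scan count L.
#' @export
trace_length <- function(trace) nrow(trace$intensities)

#' Called-base string of a trace
#' @param trace A `trace_signal`.
#' @return Single string of called bases.
#' @export
called_sequence <- function(trace) paste(trace$basecalls$base, collapse = "")

#' Read a four-channel trace from the plain-text TSV dialect
#'
#' The on-disk dialect is a UTF-8 tab-separated file with a header line
#' `pos A C G T`, one row per scan index, followed by a line `# basecalls`
#' and a second tab-separated block with header `index base peak_pos` and one
#' row per called base. All indices are 0-based.
#'
#' @param path Path to a trace file.
#' @param dialect File dialect; only `"tsv"` (the dialect above) is
#'   supported.
#' @return A [trace_signal()].
#' @export
read_trace <- function(path, dialect = c("tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("trace file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  sep <- which(trimws(lines) == "# basecalls")
  if (length(sep) != 1) {
    abort("trace file must contain exactly one `# basecalls` block",
      class = "epimem_format_error"
    )
  }
  if (sep < 2 || sep == length(lines)) {
    abort("trace file has an empty intensity or basecall block",
      class = "epimem_format_error"
    )
  }
  ints <- readr::read_tsv(
    I(paste(lines[1:(sep - 1)], collapse = "\n")),
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  missing <- setdiff(c("pos", trace_channels), names(ints))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "trace intensity block is missing column(s): %s",
        paste(missing, collapse = ", ")
      ),
      class = "epimem_format_error"
    )
  }
  extra <- setdiff(names(ints), c("pos", trace_channels))
  if (length(extra) > 0) {
    abort(
      sprintf(
        "trace intensity block has unexpected column(s): %s",
        paste(extra, collapse = ", ")
      ),
      class = "epimem_format_error"
    )
  }
  bc <- readr::read_tsv(
    I(paste(lines[(sep + 1):length(lines)], collapse = "\n")),
    col_types = readr::cols(
      index = readr::col_integer(),
      base = readr::col_character(),
      peak_pos = readr::col_integer()
    ),
    progress = FALSE
  )
  missing_bc <- setdiff(c("index", "base", "peak_pos"), names(bc))
  if (length(missing_bc) > 0) {
    abort(
      sprintf(
        "basecall block is missing column(s): %s",
        paste(missing_bc, collapse = ", ")
      ),
      class = "epimem_format_error"
    )
  }
  ints$pos <- as.integer(ints$pos)
  trace_signal(ints, bc)
}

#' Write a trace to the plain-text TSV dialect
#'
#' Refuses to write a trace that violates the `trace_signal` invariants, so
#' any file produced is readable by [read_trace()] and round-trips to an
#' equal object.
#'
#' @param trace A valid [trace_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "trace_signal")) {
    abort("`trace` must be a trace_signal")
  }
  validate_trace_signal(trace)
  ints <- trace$intensities
  head_block <- c(
    paste(c("pos", trace_channels), collapse = "\t"),
    sprintf(
      "%d\t%.10g\t%.10g\t%.10g\t%.10g",
      ints$pos, ints$A, ints$C, ints$G, ints$T
    )
  )
  bc <- trace$basecalls
  bc_block <- c(
    "# basecalls",
    "index\tbase\tpeak_pos",
    sprintf("%d\t%s\t%d", bc$index, bc$base, bc$peak_pos)
  )
  writeLines(c(head_block, bc_block), path, useBytes = TRUE)
  invisible(path)
}

#' SNP locus descriptor
#'
#' Describes the biallelic single-nucleotide difference used to distinguish
#' two pooled strains, together with the called-base context expected on
#' either side of the variant position.
#'
#' @param allele_primary,allele_secondary The two alleles (distinct single
#'   bases among A, C, G, T); "primary" is the allele whose fraction is
#'   reported.
#' @param flank_left,flank_right Nonempty base strings expected immediately
#'   left/right of the SNP in the called sequence.
#' @param label Free-text label.
#' @return An object of class `snp_locus`.
#' @export
#' @examples
#' snp_locus("A", "C", "TTGGA", "CCATT", label = "URA3-integrated SNP")
snp_locus <- function(allele_primary, allele_secondary,
                      flank_left, flank_right, label = "") {
  ok_base <- function(b) {
    is.character(b) && length(b) == 1 && b %in% trace_channels
  }
  if (!ok_base(allele_primary) || !ok_base(allele_secondary)) {
    abort("alleles must be single bases among A, C, G, T")
  }
  if (allele_primary == allele_secondary) {
    abort("the two alleles must differ")
  }
  ok_flank <- function(f) {
    is.character(f) && length(f) == 1 && nchar(f) > 0 &&
      grepl("^[ACGT]+$", f)
  }
  if (!ok_flank(flank_left) || !ok_flank(flank_right)) {
    abort("flanks must be nonempty A/C/G/T strings")
  }
  structure(
    list(
      allele_primary = allele_primary,
      allele_secondary = allele_secondary,
      flank_left = flank_left,
      flank_right = flank_right,
      label = label
    ),
    class = "snp_locus"
  )
}

#' @export
print.snp_locus <- function(x, ...) {
  cat(sprintf(
    "<snp_locus> %s[%s/%s]%s %s\n",
    x$flank_left, x$allele_primary, x$allele_secondary, x$flank_right,
    if (nzchar(x$label)) paste0("(", x$label, ")") else ""
  ))
  invisible(x)
}

#' Read/write a SNP locus descriptor
#'
#' Small key-value text format: one `key<TAB>value` pair per line with keys
#' `allele_primary`, `allele_secondary`, `flank_left`, `flank_right`,
#' and optional `label`.
#'
#' @param path File path.
#' @return `read_snp_locus` returns a [snp_locus()]; `write_snp_locus`
#'   returns `path` invisibly.
#' @export
read_snp_locus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed key-value line %d in %s", bad[1], path),
      class = "epimem_format_error"
    )
  }
  kv <- setNames(
    vapply(parts, `[[`, "", 2),
    vapply(parts, `[[`, "", 1)
  )
  need <- c("allele_primary", "allele_secondary", "flank_left", "flank_right")
  missing <- setdiff(need, names(kv))
  if (length(missing) > 0) {
    abort(
      sprintf("locus file missing key(s): %s", paste(missing, collapse = ", ")),
      class = "epimem_format_error"
    )
  }
  snp_locus(
    kv[["allele_primary"]], kv[["allele_secondary"]],
    kv[["flank_left"]], kv[["flank_right"]],
    label = if ("label" %in% names(kv)) kv[["label"]] else ""
  )
}

#' @param locus A [snp_locus()].
#' @rdname read_snp_locus
#' @export
write_snp_locus <- function(locus, path) {
  stopifnot(inherits(locus, "snp_locus"))
  writeLines(
    c(
      paste0("allele_primary\t", locus$allele_primary),
      paste0("allele_secondary\t", locus$allele_secondary),
      paste0("flank_left\t", locus$flank_left),
      paste0("flank_right\t", locus$flank_right),
      paste0("label\t", locus$label)
    ),
    path,
    useBytes = TRUE
  )
  invisible(path)
}
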