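#' Read genomic intervals from a BED file
#'
#' Reads BED 3-6 into a tibble of 0-based half-open intervals. Columns beyond
#' the sixth are ignored. For peak files the score column is interpreted
#' throughout the package as -log10(p) of the peak call.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`. Missing optional fields default to `name = "."`, `score = NA`,
#'   `strand = "."`.
#' @details Malformed lines (fewer than 3 fields, non-integer coordinates,
#'   `end <= start`, negative `start`) raise an error naming the offending
#'   line number. Chromosome names are kept verbatim; no "chr" normalisation
#'   is attempted.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tsrf1\t8.0\t.", tf)
#' read_bed(tf)
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- keep[which(nf < 3L)[1]]
    abort(sprintf("BED parse error at line %d: fewer than 3 tab-separated fields", bad))
  }
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(col(2L, NA)))
  end <- suppressWarnings(as.numeric(col(3L, NA)))
  bad_coord <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad_coord) > 0L) {
    abort(sprintf("BED parse error at line %d: non-integer coordinates", keep[bad_coord[1]]))
  }
  bad_iv <- which(end <= start | start < 0)
  if (length(bad_iv) > 0L) {
    abort(sprintf(
      "BED parse error at line %d: invalid interval (need 0 <= start < end)",
      keep[bad_iv[1]]
    ))
  }
  score_chr <- col(5L, NA_character_)
  score <- suppressWarnings(as.numeric(score_chr))
  score[score_chr %in% "."] <- NA_real_
  strand <- col(6L, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  tibble(
    chrom = col(1L, NA_character_),
    start = as.integer(start),
    end = as.integer(end),
    name = ifelse(is.na(col(4L, NA_character_)), ".", col(4L, NA_character_)),
    score = score,
    strand = strand
  )
}

#' Write genomic intervals to a BED file
#'
#' @param x A tibble of intervals as returned by [read_bed()]; only `chrom`,
#'   `start`, `end` are required.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  out <- tibble(
    chrom = as.character(x$chrom),
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = if ("name" %in% names(x)) as.character(x$name) else ".",
    score = if ("score" %in% names(x)) x$score else NA_real_,
    strand = if ("strand" %in% names(x)) as.character(x$strand) else "."
  )
  out$score <- ifelse(is.na(out$score), ".", format(out$score, trim = TRUE, scientific = FALSE))
  readr::write_tsv(out, path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Read a gene-level count table
#'
#' Expects a TSV whose first column holds gene identifiers and whose remaining
#' columns are samples; the header row carries the sample descriptors (see
#' [parse_samples()] for the naming convention the simulator emits).
#'
#' @param path Path to the TSV.
#' @return A wide tibble: `gene_id` plus one non-negative integer column per
#'   sample.
#' @export
read_counts <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  for (j in seq_along(x)[-1]) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    if (anyNA(v) && !all(is.na(x[[j]]) == is.na(v))) {
      abort("count table parse error: non-numeric count")
    }
    x[[j]] <- v
  }
  if (anyDuplicated(x$gene_id) > 0L) {
    dup <- x$gene_id[duplicated(x$gene_id)][1]
    abort(sprintf("count table parse error: duplicate gene id '%s'", dup))
  }
  cnt <- as.matrix(x[, -1, drop = FALSE])
  if (anyNA(cnt)) abort("count table parse error: non-numeric count")
  if (any(cnt < 0)) abort("count table parse error: negative count")
  if (any(cnt != floor(cnt))) abort("count table parse error: non-integer count")
  for (j in seq_along(x)[-1]) x[[j]] <- as.integer(x[[j]])
  as_tibble(x)
}

#' Write a gene-level count table
#'
#' @param x Wide count tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(names(x)[1] == "gene_id")
  readr::write_tsv(x, path, escape = "none")
  invisible(path)
}

#' Parse sample descriptors from count-table column names
#'
#' Sample columns are named `<background>_<condition>_<replicate>_<read_class>`,
#' e.g. `WT_TPA_1_total` or `TKO.Elk1_resting_2_intronic`. Backgrounds must not
#' contain underscores.
#'
#' @param sample_names Character vector of sample column names.
#' @return A tibble with columns `sample`, `background`, `condition`,
#'   `replicate` (integer), `read_class`.
#' @export
parse_samples <- function(sample_names) {
  parts <- strsplit(sample_names, "_", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "sample name '%s' is not of the form background_condition_replicate_readclass",
      sample_names[bad[1]]
    ))
  }
  m <- do.call(rbind, parts)
  tibble(
    sample = sample_names,
    background = m[, 1],
    condition = m[, 2],
    replicate = as.integer(m[, 3]),
    read_class = m[, 4]
  )
}

#' Construct a sparse intra-chromosomal contact map
#'
#' @param entries Tibble with columns `chrom`, `bin_i`, `bin_j`, `count`.
#'   Entries are canonicalised so `bin_i <= bin_j` and duplicate pairs are
#'   accumulated; zero-count entries are dropped.
#' @param bin_size Bin width in bp (default 10,000).
#' @return A `contact_map`: a tibble of canonical entries with a `bin_size`
#'   attribute.
#' @export
contact_map <- function(entries, bin_size = 10000L) {
  stopifnot(all(c("chrom", "bin_i", "bin_j", "count") %in% names(entries)),
            bin_size > 0)
  if (any(entries$bin_i < 0 | entries$bin_j < 0)) abort("bin indices must be >= 0")
  if (any(entries$count < 0)) abort("contact counts must be >= 0")
  out <- entries |>
    mutate(
      i = pmin(.data$bin_i, .data$bin_j),
      j = pmax(.data$bin_i, .data$bin_j)
    ) |>
    group_by(.data$chrom, .data$i, .data$j) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0) |>
    rename(bin_i = "i", bin_j = "j") |>
    arrange(.data$chrom, .data$bin_i, .data$bin_j)
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("contact_map", class(out))
  out
}

#' Bin width of a contact map
#' @param map A `contact_map`.
#' @return Bin size in bp.
#' @export
map_bin_size <- function(map) {
  bs <- attr(map, "bin_size")
  if (is.null(bs)) abort("not a contact_map: missing bin_size attribute")
  bs
}

#' Read Hi-C contacts from text
#'
#' Two dialects are supported. `mode = "pairs"`: each line is
#' `chrom  pos1  pos2`, one intra-chromosomal read pair; positions are
#' assigned to bins by `floor(pos / bin_size)` and each line contributes one
#' count. `mode = "triplets"`: each line is `chrom  bin_i  bin_j  count`,
#' already binned. In both dialects (i, j) and (j, i) accumulate into the
#' same canonical entry with `bin_i <= bin_j`.
#'
#' @param path Input path.
#' @param bin_size Bin width in bp.
#' @param mode `"pairs"` or `"triplets"`.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, bin_size = 10000L, mode = c("pairs", "triplets")) {
  mode <- match.arg(mode)
  stopifnot(file.exists(path))
  ncols <- if (mode == "pairs") 3L else 4L
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         X1 = readr::col_character(),
                         .default = readr::col_double()
                       ))
  if (nrow(x) == 0L) {
    return(contact_map(tibble(chrom = character(), bin_i = integer(),
                              bin_j = integer(), count = double()),
                       bin_size = bin_size))
  }
  if (ncol(x) < ncols) {
    abort(sprintf("contact parse error: expected %d columns for mode '%s'", ncols, mode))
  }
  if (mode == "pairs") {
    if (any(x[[2]] < 0 | x[[3]] < 0)) abort("contact parse error: negative position")
    ent <- tibble(
      chrom = x[[1]],
      bin_i = as.integer(x[[2]] %/% bin_size),
      bin_j = as.integer(x[[3]] %/% bin_size),
      count = 1
    )
  } else {
    ent <- tibble(
      chrom = x[[1]],
      bin_i = as.integer(x[[2]]),
      bin_j = as.integer(x[[3]]),
      count = x[[4]]
    )
  }
  contact_map(ent, bin_size = bin_size)
}

#' Write Hi-C contacts as binned triplets
#'
#' Emits the 4-column `chrom  bin_i  bin_j  count` dialect read back by
#' `read_contacts(mode = "triplets")`.
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(map, path) {
  readr::write_tsv(as_tibble(map)[, c("chrom", "bin_i", "bin_j", "count")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Peak summit positions
#'
#' The summit of a peak is the value of its `summit` column when present,
#' otherwise the interval midpoint `floor((start + end) / 2)`.
#'
#' @param peaks Interval tibble.
#' @return Integer vector of summit positions (0-based).
#' @export
peak_summit <- function(peaks) {
  if ("summit" %in% names(peaks) && !all(is.na(peaks$summit))) {
    out <- ifelse(is.na(peaks$summit),
                  (peaks$start + peaks$end) %/% 2L,
                  peaks$summit)
    return(as.integer(out))
  }
  as.integer((peaks$start + peaks$end) %/% 2L)
}

#' Transcription start site positions
#'
#' For a +-strand (or unstranded) interval the TSS is `start`; for a --strand
#' interval it is `end - 1` (the last base of the 0-based half-open interval).
#'
#' @param tss Interval tibble with a `strand` column.
#' @return Integer vector of TSS base positions.
#' @export
tss_position <- function(tss) {
  strand <- if ("strand" %in% names(tss)) tss$strand else "."
  as.integer(ifelse(strand == "-", tss$end - 1L, tss$start))
}

#' Assign positions to fixed-width bins
#'
#' @param pos Base positions (0-based).
#' @param bin_size Bin width in bp.
#' @return Integer bin indices `floor(pos / bin_size)`.
#' @export
bin_of <- function(pos, bin_size) {
  as.integer(pos %/% bin_size)
}

# Internal: interval tibble -> GRanges (1-based closed, as GenomicRanges expects)
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) sub("^\\.$", "*", x$strand) else "*"
  )
}
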