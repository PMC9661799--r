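#' Genome layout for segmented copy-number profiles
#'
#' A layout is the shared segmentation of the genome: an ordered set of
#' chromosomes, each carrying ordered, non-overlapping segments.
#' Coordinates are stored 0-based half-open internally; the TSV interface
#' uses 1-based inclusive coordinates (the common segment-table dialect).
#'
#' @param chrom character vector of chromosome names (one per segment, in
#'   layout order).
#' @param start,end integer vectors of 0-based half-open segment bounds.
#' @return an object of class `cn_layout`: a data.frame with columns
#'   `chrom`, `start`, `end`.
#' @export
cn_layout <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("segment start must be < end")
  for (ch in unique(df$chrom)) {
    seg <- df[df$chrom == ch, ]
    if (is.unsorted(seg$start, strictly = TRUE) ||
        any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("segments within a chromosome must be sorted and non-overlapping")
  }
  class(df) <- c("cn_layout", "data.frame")
  df
}

layout_chroms <- function(layout) unique(layout$chrom)
layout_nseg <- function(layout) nrow(layout)
layout_seg_lengths <- function(layout) layout$end - layout$start

#' Haplotype-specific copy-number profile
#'
#' Two integer copy-number vectors (haplotypes A and B) over a shared
#' genome layout.  Values satisfy `0 <= k <= cap`.
#'
#' @param sample_id sample name.
#' @param hapA,hapB integer copy numbers per layout segment.
#' @param cap maximum representable copy number (default 8).
#' @return an object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, hapA, hapB, cap = 8L) {
  hapA <- as.integer(hapA); hapB <- as.integer(hapB)
  stopifnot(length(hapA) == length(hapB))
  if (any(c(hapA, hapB) < 0)) stop("negative copy number")
  if (any(c(hapA, hapB) > cap)) stop("copy number above cap; clip first")
  structure(list(sample_id = sample_id, hapA = hapA, hapB = hapB,
                 cap = as.integer(cap)), class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile '%s': %d segments, cap %d>\n", x$sample_id,
              length(x$hapA), x$cap))
  invisible(x)
}

#' Diploid reference profile on a layout
#'
#' All segments at copy number 1 on both haplotypes; used as the
#' phylogenetic root and phasing reference.
#'
#' @param layout a `cn_layout`.
#' @param cap maximum copy number.
#' @export
diploid_profile <- function(layout, cap = 8L) {
  n <- layout_nseg(layout)
  cn_profile("diploid", rep(1L, n), rep(1L, n), cap = cap)
}

#' Cohort of copy-number profiles on one shared layout
#'
#' @param layout a `cn_layout`.
#' @param profiles list of `cn_profile`s with unique sample ids (the
#'   diploid is appended automatically if absent).
#' @param cap maximum copy number.
#' @return an object of class `cn_cohort` with elements `layout`,
#'   `profiles` (named list, diploid last) and `cap`.
#' @export
cn_cohort <- function(layout, profiles, cap = 8L) {
  n <- layout_nseg(layout)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  for (p in profiles)
    if (length(p$hapA) != n)
      stop("profile length does not match layout segment count")
  if (!"diploid" %in% ids)
    profiles <- c(profiles, list(diploid_profile(layout, cap)))
  names(profiles) <- vapply(profiles, `[[`, "", "sample_id")
  structure(list(layout = layout, profiles = profiles, cap = as.integer(cap)),
            class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat(sprintf("<cn_cohort: %d profiles (incl. diploid), %d segments on %d chromosomes, cap %d>\n",
              length(x$profiles), layout_nseg(x$layout),
              length(layout_chroms(x$layout)), x$cap))
  invisible(x)
}

#' Read a cohort of allele-specific copy-number segments from TSV
#'
#' Expects a tab-separated file with header columns `sample_id`, `chrom`,
#' `start`, `end` and two allele columns (1-based inclusive coordinates).
#' All samples must share one segmentation; otherwise an error points to
#' [harmonize_segmentation()].  Copy numbers above `cap` are clipped with a
#' warning; negative values are an error.  Sex chromosomes (X, Y, chrX,
#' chrY) are excluded unless `include_sex = TRUE`.
#'
#' @param path file path.
#' @param allele_columns names of the two allele columns.
#' @param cap maximum copy number; values above it are clipped.
#' @param include_sex keep sex chromosomes (default drops them).
#' @return a `cn_cohort` (diploid appended).
#' @export
read_cohort_tsv <- function(path, allele_columns = c("cn_a", "cn_b"),
                            cap = 8L, include_sex = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "chrom", "start", "end", allele_columns)
  if (!all(need %in% names(df)))
    stop("TSV must contain columns: ", paste(need, collapse = ", "))
  if (!include_sex)
    df <- df[!df$chrom %in% c("X", "Y", "chrX", "chrY"), , drop = FALSE]
  if (nrow(df) == 0) stop("no rows after filtering")
  cohort_from_segments(df, allele_columns, cap = cap, one_based = TRUE)
}

cohort_from_segments <- function(df, allele_columns = c("cn_a", "cn_b"),
                                 cap = 8L, one_based = TRUE) {
  a <- df[[allele_columns[1]]]; b <- df[[allele_columns[2]]]
  if (any(a < 0) || any(b < 0)) stop("negative copy number")
  nclip <- sum(a > cap) + sum(b > cap)
  if (nclip > 0) {
    warning(sprintf("%d copy-number values above cap %d were clipped", nclip, cap))
    a <- pmin(a, cap); b <- pmin(b, cap)
  }
  if (one_based) df$start <- df$start - 1  # to 0-based half-open
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  samples <- unique(df$sample_id)
  ref <- df[df$sample_id == samples[1], ]
  ord <- order(match(ref$chrom, unique(df$chrom)), ref$start)
  ref <- ref[ord, ]
  refkey <- key(ref)
  profs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sub <- df[df$sample_id == samples[i], ]
    sub <- sub[order(match(sub$chrom, unique(df$chrom)), sub$start), ]
    if (nrow(sub) != nrow(ref) || !all(key(sub) == refkey))
      stop("samples have differing segmentations; run harmonize_segmentation() first")
    aa <- pmin(sub[[allele_columns[1]]], cap)
    bb <- pmin(sub[[allele_columns[2]]], cap)
    profs[[i]] <- cn_profile(samples[i], aa, bb, cap = cap)
  }
  layout <- cn_layout(ref$chrom, ref$start, ref$end)
  cn_cohort(layout, profs, cap = cap)
}

#' Harmonize per-sample segmentations onto a common breakpoint union
#'
#' The common layout is the union of all samples' breakpoints; each
#' sample's copy numbers are carried onto every sub-segment they span.
#' Total genome length is conserved.
#'
#' @param tables named list of per-sample data.frames with columns `chrom`,
#'   `start`, `end` and the two allele columns (0-based half-open, or
#'   1-based inclusive with `one_based = TRUE`).
#' @param allele_columns names of the two allele columns.
#' @param cap maximum copy number.
#' @param one_based whether the inputs use 1-based inclusive coordinates.
#' @return a `cn_cohort` on the harmonized layout.
#' @export
harmonize_segmentation <- function(tables, allele_columns = c("cn_a", "cn_b"),
                                   cap = 8L, one_based = FALSE) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  tabs <- lapply(tables, function(t) {
    t <- t[order(match(t$chrom, unique(t$chrom)), t$start), , drop = FALSE]
    if (one_based) t$start <- t$start - 1
    t
  })
  chroms <- unique(unlist(lapply(tabs, function(t) unique(t$chrom))))
  # chromosome extents must agree where samples overlap
  pieces <- list()
  for (ch in chroms) {
    bps <- sort(unique(unlist(lapply(tabs, function(t) {
      s <- t[t$chrom == ch, ]; c(s$start, s$end)
    }))))
    if (length(bps) < 2) next
    pieces[[ch]] <- data.frame(chrom = ch, start = bps[-length(bps)],
                               end = bps[-1], stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, pieces)
  rownames(lay) <- NULL
  profs <- vector("list", length(tabs))
  for (i in seq_along(tabs)) {
    t <- tabs[[i]]
    a <- rep(NA_integer_, nrow(lay)); b <- a
    for (r in seq_len(nrow(t))) {
      hit <- lay$chrom == t$chrom[r] & lay$start >= t$start[r] &
        lay$end <= t$end[r]
      bad <- lay$chrom == t$chrom[r] & !hit &
        lay$start < t$end[r] & lay$end > t$start[r]
      if (any(bad)) stop("partially overlapping segments with conflicting bounds")
      a[hit] <- t[[allele_columns[1]]][r]
      b[hit] <- t[[allele_columns[2]]][r]
    }
    if (anyNA(a) || anyNA(b))
      stop(sprintf("sample '%s' does not cover the union layout", names(tabs)[i]))
    nclip <- sum(a > cap) + sum(b > cap)
    if (nclip > 0)
      warning(sprintf("%d values clipped to cap %d", nclip, cap))
    profs[[i]] <- cn_profile(names(tabs)[i], pmin(a, cap), pmin(b, cap),
                             cap = cap)
  }
  cn_cohort(cn_layout(lay$chrom, lay$start, lay$end), profs, cap = cap)
}

#' Write a cohort back to the TSV dialect of [read_cohort_tsv()]
#'
#' @param cohort a `cn_cohort`.
#' @param path output file path.
#' @param include_diploid also write the diploid reference rows.
#' @export
write_cohort_tsv <- function(cohort, path, include_diploid = FALSE) {
  lay <- cohort$layout
  rows <- lapply(cohort$profiles, function(p) {
    if (!include_diploid && p$sample_id == "diploid") return(NULL)
    data.frame(sample_id = p$sample_id, chrom = lay$chrom,
               start = lay$start + 1, end = lay$end, cn_a = p$hapA,
               cn_b = p$hapB, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- symbol encoding ---------------------------------------------------

#' Symbol code of the chromosome separator for a given cap
#' @param cap maximum copy number.
#' @export
x_symbol <- function(cap = 8L) as.integer(cap + 1L)

#' Alphabet size for a given cap (copy numbers 0..cap plus "X")
#' @param cap maximum copy number.
#' @export
n_symbols_for_cap <- function(cap = 8L) as.integer(cap + 2L)

# encode one haplotype vector as chromosome blocks separated by X
encode_hap <- function(v, layout, cap) {
  X <- x_symbol(cap)
  chroms <- layout_chroms(layout)
  blocks <- lapply(chroms, function(ch) v[layout$chrom == ch])
  out <- blocks[[1]]
  if (length(blocks) > 1)
    for (i in 2:length(blocks)) out <- c(out, X, blocks[[i]])
  out
}

#' Encode a profile as a symbol string over {0..cap, X}
#'
#' Haplotype A's chromosomes in layout order with "X" between chromosomes,
#' then one "X", then haplotype B likewise; no leading or trailing
#' separator.  `decode_profile(encode_profile(p)) == p` exactly.
#'
#' @param profile a `cn_profile`.
#' @param layout the shared `cn_layout`.
#' @return integer vector of symbol codes.
#' @export
encode_profile <- function(profile, layout) {
  stopifnot(length(profile$hapA) == layout_nseg(layout))
  cap <- profile$cap
  c(encode_hap(profile$hapA, layout, cap), x_symbol(cap),
    encode_hap(profile$hapB, layout, cap))
}

#' Decode a symbol string back into a profile
#'
#' @param symbols integer symbol codes as produced by [encode_profile()].
#' @param layout the `cn_layout` the symbols were encoded on.
#' @param cap maximum copy number.
#' @param sample_id name for the decoded profile.
#' @return a `cn_profile`.
#' @export
decode_profile <- function(symbols, layout, cap = 8L, sample_id = "decoded") {
  X <- x_symbol(cap)
  n <- layout_nseg(layout)
  vals <- symbols[symbols != X]
  if (length(vals) != 2 * n) stop("symbol string does not match layout")
  nx <- sum(symbols == X)
  if (nx != 2 * length(layout_chroms(layout)) - 1)
    stop("unexpected number of separator symbols")
  cn_profile(sample_id, vals[seq_len(n)], vals[n + seq_len(n)], cap = cap)
}

# per-position metadata of the encoded string: haplotype, chrom, segment
encoding_map <- function(layout) {
  chroms <- layout_chroms(layout)
  one <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    idx <- which(layout$chrom == chroms[i])
    d <- data.frame(hap = NA_character_, chrom = chroms[i], seg = idx,
                    stringsAsFactors = FALSE)
    if (i < length(chroms))
      d <- rbind(d, data.frame(hap = NA, chrom = NA, seg = NA))
    d
  }))
  both <- rbind(transform(one, hap = ifelse(is.na(seg), NA, "A")),
                data.frame(hap = NA, chrom = NA, seg = NA),
                transform(one, hap = ifelse(is.na(seg), NA, "B")))
  rownames(both) <- NULL
  both
}

#' Ploidy and LOH summaries of a profile
#'
#' Ploidy is the length-weighted mean total copy number; `fraction_LOH` is
#' the length-weighted fraction of the genome where one haplotype is at
#' copy number zero.
#'
#' @param profile a `cn_profile`.
#' @param layout the shared `cn_layout`.
#' @return a list with `ploidy` and `fraction_LOH`.
#' @export
profile_summaries <- function(profile, layout) {
  w <- layout_seg_lengths(layout)
  tot <- profile$hapA + profile$hapB
  list(ploidy = sum(w * tot) / sum(w),
       fraction_LOH = sum(w * (pmin(profile$hapA, profile$hapB) == 0)) / sum(w))
}
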