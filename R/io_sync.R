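#' @title Pooled allele counts in sync format
#' @description
#' The sync format (PoPoolation2 dialect) is the tab-separated interchange
#' for pooled allele counts: one line per site with columns
#' `chrom`, `pos` (1-based), `ref`, then one `A:T:C:G:N:del` count column
#' per pool. `read_sync()` parses and validates a file against a declared
#' pool layout; `write_sync()` serializes a `pool_sync` object losslessly.
#'
#' A `pool_sync` object is a list with
#' * `sites`: data.frame with `chrom`, `pos`, `ref`;
#' * `counts`: integer array `[site, pool, base]` with base order
#'   A, T, C, G, N, del;
#' * `layout`: data.frame with one row per pool: `group`, `replicate`,
#'   `n_ind` (diploid individuals in the pool).
#'
#' @param path file path.
#' @param pool_labels data.frame with one row per pool column, in file
#'   order, with columns `group`, `replicate` and optionally `n_ind`
#'   (default 16).
#' @return `read_sync()` returns a `pool_sync` object.
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("chr1\t100\tA\t16:4:0:0:0:0\t10:10:0:0:0:0", f)
#' s <- read_sync(f, data.frame(group = c("L", "H"), replicate = c(1, 1)))
#' s$counts[1, , ]
#' @export
read_sync <- function(path, pool_labels) {
  stopifnot(is.data.frame(pool_labels),
            all(c("group", "replicate") %in% names(pool_labels)))
  if (is.null(pool_labels$n_ind)) pool_labels$n_ind <- 16L
  n_pool <- nrow(pool_labels)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_pool_sync(
      sites = data.frame(chrom = character(), pos = integer(),
                         ref = character(), stringsAsFactors = FALSE),
      counts = array(0L, dim = c(0L, n_pool, 6L)),
      layout = pool_labels))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L + n_pool)
  if (length(bad))
    .fail("sync parse error: line %d has %d pool column(s), layout declares %d",
          bad[1], nf[bad[1]] - 3L, n_pool)
  m <- matrix(unlist(fields), ncol = 3L + n_pool, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1L))
    .fail("sync parse error: line %d has invalid position '%s'",
          which(is.na(pos) | pos < 1L)[1], m[which(is.na(pos) | pos < 1L)[1], 2])
  counts <- array(0L, dim = c(nrow(m), n_pool, 6L),
                  dimnames = list(NULL, NULL, SYNC_BASES))
  for (j in seq_len(n_pool)) {
    col <- m[, 3L + j]
    ok <- grepl("^[0-9]+(:[0-9]+){5}$", col)
    if (!all(ok))
      .fail("sync parse error: line %d pool %d has malformed count field '%s'",
            which(!ok)[1], j, col[which(!ok)[1]])
    counts[, j, ] <- matrix(as.integer(unlist(strsplit(col, ":", fixed = TRUE))),
                            ncol = 6L, byrow = TRUE)
  }
  new_pool_sync(
    sites = data.frame(chrom = m[, 1], pos = pos, ref = toupper(m[, 3]),
                       stringsAsFactors = FALSE),
    counts = counts, layout = pool_labels)
}

#' @rdname read_sync
#' @param x a `pool_sync` object.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "pool_sync"))
  n <- nrow(x$sites)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- vapply(seq_len(dim(x$counts)[2]), function(j) {
    apply(x$counts[, j, , drop = FALSE], 1, function(v) paste(v, collapse = ":"))
  }, character(n))
  lines <- do.call(paste, c(list(x$sites$chrom, x$sites$pos, x$sites$ref),
                            split(cols, col(cols)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

new_pool_sync <- function(sites, counts, layout) {
  stopifnot(nrow(sites) == dim(counts)[1], nrow(layout) == dim(counts)[2])
  if (any(counts < 0)) .fail("pool_sync: negative counts")
  structure(list(sites = sites, counts = counts, layout = layout),
            class = "pool_sync")
}

#' @export
print.pool_sync <- function(x, ...) {
  cat(sprintf("pool_sync: %d sites x %d pools (groups: %s)\n",
              nrow(x$sites), nrow(x$layout),
              paste(unique(x$layout$group), collapse = ", ")))
  invisible(x)
}

#' Reduce sync counts to a biallelic (ref, alt) pair per site
#'
#' At each site the reference base plus the most frequent non-reference
#' base (summed over all pools, among A/C/G/T) define the allele pair.
#' Sites where any remaining third allele exceeds `max_third_frac` of the
#' total A/C/G/T reads are flagged and excluded, as are sites whose
#' reference base is not one of A/C/G/T. The N and deletion columns are
#' ignored: the screen is SNP-only.
#'
#' @param x a `pool_sync` object.
#' @param max_third_frac maximum tolerated third-allele fraction (default
#'   0.05).
#' @return list with `ref_counts` and `alt_counts` (site x pool integer
#'   matrices), `alt` (alt base per site), `keep` (logical), and
#'   `n_excluded_triallelic`.
#' @export
biallelic_reduce <- function(x, max_third_frac = 0.05) {
  stopifnot(inherits(x, "pool_sync"))
  nuc <- c("A", "T", "C", "G")
  n <- nrow(x$sites)
  if (n == 0L) {
    return(list(ref_counts = matrix(0L, 0, nrow(x$layout)),
                alt_counts = matrix(0L, 0, nrow(x$layout)),
                alt = character(), keep = logical(),
                n_excluded_triallelic = 0L))
  }
  tot_by_base <- sapply(nuc, function(b) rowSums(x$counts[, , b, drop = FALSE]))
  tot_by_base <- matrix(tot_by_base, nrow = n,
                        dimnames = list(NULL, nuc))
  ref_idx <- match(x$sites$ref, nuc)
  valid_ref <- !is.na(ref_idx)
  nonref <- tot_by_base
  nonref[cbind(seq_len(n)[valid_ref], ref_idx[valid_ref])] <- -1L
  alt_idx <- max.col(nonref, ties.method = "first")
  alt <- nuc[alt_idx]
  total <- rowSums(tot_by_base)
  ref_tot <- rep(0, n)
  ref_tot[valid_ref] <- tot_by_base[cbind(which(valid_ref), ref_idx[valid_ref])]
  alt_tot <- tot_by_base[cbind(seq_len(n), alt_idx)]
  third <- total - ref_tot - alt_tot
  keep <- valid_ref & (total == 0 | third <= max_third_frac * total)
  ref_counts <- matrix(0L, n, nrow(x$layout))
  alt_counts <- matrix(0L, n, nrow(x$layout))
  for (j in seq_len(nrow(x$layout))) {
    slab <- matrix(x$counts[, j, c("A", "T", "C", "G")], nrow = n)
    ref_counts[valid_ref, j] <- slab[cbind(which(valid_ref), ref_idx[valid_ref])]
    alt_counts[, j] <- slab[cbind(seq_len(n), alt_idx)]
  }
  list(ref_counts = ref_counts, alt_counts = alt_counts, alt = alt,
       keep = keep, n_excluded_triallelic = sum(!keep))
}
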