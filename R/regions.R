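# Connected-component labeling on a logical matrix via an explicit
# pixel-adjacency edge list and igraph's component search. Returns an
# integer matrix of labels (0 = background), numbered 1..nComponents.
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  edges <- integer(0)
  addEdges <- function(ok, off) {
    nb <- idx[ok] + off
    hit <- mask[nb]
    if (any(hit))
      rbind(rank[idx[ok][hit]], rank[nb[hit]])
    else NULL
  }
  shifts <- list(list(r < nr - 1L, 1L),            # down
                 list(cc < nc - 1L, nr))           # right
  if (connectivity == 8L)
    shifts <- c(shifts,
                list(list(r < nr - 1L & cc < nc - 1L, nr + 1L),  # down-right
                     list(r > 0L & cc < nc - 1L, nr - 1L)))      # up-right
  em <- do.call(cbind, Filter(Negate(is.null), lapply(shifts, function(s)
    addEdges(s[[1]], s[[2]]))))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em))
    g <- igraph::add_edges(g, as.vector(em))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Partition the union of two raters' masks into classified regions
#'
#' Per slice, forms the binary OR of the two masks, enumerates its
#' connected components (default 8-connectivity, so a thin diagonal
#' outline cannot split one lesion into several regions), and classifies
#' each component as CR1 (pixels from rater 1 only), CR2 (rater 2 only)
#' or CR12 (formed by both raters). Multiple outlines of the same rater
#' falling into one union component are merged; components are never
#' merged across slices. Every foreground pixel of either rater belongs
#' to exactly one region.
#'
#' @param pair a \linkS4class{RaterMaskPair}
#' @param connectivity 8 (default) or 4
#' @return a region table: data.frame with columns scan_id, slice
#'   (1-based plane), label, area_union, area_r1, area_r2,
#'   area_intersection; areas in mm^2
#' @export
partitionRegions <- function(pair, connectivity = 8L) {
  stopifnot(is(pair, "RaterMaskPair"))
  validObject(pair)
  pa <- pixelArea(pair@geometry)
  nsl <- dim(pair@rater1)[3]
  out <- vector("list", nsl)
  for (s in seq_len(nsl)) {
    m1 <- pair@rater1[, , s]
    m2 <- pair@rater2[, , s]
    lab <- labelComponents(m1 | m2, connectivity)
    k <- max(lab)
    if (k == 0L) next
    fg <- lab > 0L
    l <- lab[fg]
    cntU <- tabulate(l, k)
    cnt1 <- tabulate(l[m1[fg]], k)
    cnt2 <- tabulate(l[m2[fg]], k)
    cntI <- tabulate(l[(m1 & m2)[fg]], k)
    label <- ifelse(cnt1 > 0L & cnt2 > 0L, "CR12",
                    ifelse(cnt1 > 0L, "CR1", "CR2"))
    out[[s]] <- data.frame(scan_id = pair@scanId, slice = s,
                           label = label,
                           area_union = cntU * pa, area_r1 = cnt1 * pa,
                           area_r2 = cnt2 * pa,
                           area_intersection = cntI * pa,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(emptyRegionTable())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count regions by class
#'
#' @param regions a region table from \code{\link{partitionRegions}}
#' @return named integer vector c(CR1 =, CR2 =, CR12 =)
#' @export
regionCounts <- function(regions) {
  checkRegionTable(regions)
  c(CR1 = sum(regions$label == "CR1"),
    CR2 = sum(regions$label == "CR2"),
    CR12 = sum(regions$label == "CR12"))
}

#' Export a region table as TSV
#'
#' Areas are written in mm^2 with 1 decimal, matching the reporting
#' precision used throughout; full precision stays in the in-memory table.
#'
#' @param regions a region table
#' @param path output path
#' @export
writeRegionTable <- function(regions, path) {
  checkRegionTable(regions)
  out <- regions
  for (col in c("area_union", "area_r1", "area_r2", "area_intersection"))
    out[[col]] <- sprintf("%.1f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
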