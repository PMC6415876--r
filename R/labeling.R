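# 8-connected component labelling.
#
# EBImage::bwlabel() labels 4-connected components; sperm heads and motile
# blobs must not split across diagonal contacts, so labels that touch
# diagonally are merged with a small union-find pass.
label8 <- function(mask) {
  mask <- (mask > 0) + 0
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  m <- max(lab)
  if (m <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    { a <- lab[-h, -w]; b <- lab[-1, -1]          # down-right diagonal
      s <- a > 0L & b > 0L & a != b; cbind(a[s], b[s]) },
    { a <- lab[-1, -w]; b <- lab[-h, -1]          # up-right diagonal
      s <- a > 0L & b > 0L & a != b; cbind(a[s], b[s]) })
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    i <- find(pairs[r, 1]); j <- find(pairs[r, 2])
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  root <- vapply(seq_len(m), find, numeric(1))
  newid <- match(root, sort(unique(root)))
  pos <- lab > 0L
  lab[pos] <- newid[lab[pos]]
  lab
}

# Areas/centroids/bounding boxes of labelled components.
component_stats <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer()))
  ids <- lab[pos]
  rr <- (pos - 1L) %% nrow(lab) + 1L
  cc <- (pos - 1L) %/% nrow(lab) + 1L
  m <- max(ids)
  area <- tabulate(ids, m)
  # label8 emits compact labels 1..m, so rowsum/tapply group order is 1..m
  data.frame(
    label = seq_len(m),
    area_px = area,
    centroid_row = as.numeric(rowsum(rr, ids)) / area,
    centroid_col = as.numeric(rowsum(cc, ids)) / area,
    bbox_rmin = as.integer(tapply(rr, ids, min)),
    bbox_rmax = as.integer(tapply(rr, ids, max)),
    bbox_cmin = as.integer(tapply(cc, ids, min)),
    bbox_cmax = as.integer(tapply(cc, ids, max))
  )
}
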