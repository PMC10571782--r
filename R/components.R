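# Sparse connected-component labeling with configurable 4/8 connectivity.
# Operates on the foreground pixel list (animal blobs and supra-threshold GD
# regions are sparse relative to the full grid), with union-find over
# foreground indices.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return integer matrix of the same shape: 0 for background, components
#'   numbered 1..k; attribute `n` holds k.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  n_fg <- length(fg)
  if (n_fg == 0) { attr(lab, "n") <- 0L; return(lab) }
  # index of each foreground pixel within fg, addressed by linear index
  pos <- integer(nr * nc)
  pos[fg] <- seq_len(n_fg)
  parent <- seq_len(n_fg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))           # up, left
  if (connectivity == 8)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))  # up-left, up-right
  for (off in offs) {
    nrow_i <- rows + off[1]; ncol_i <- cols + off[2]
    ok <- nrow_i >= 1L & nrow_i <= nr & ncol_i >= 1L & ncol_i <= nc
    nb <- integer(n_fg)
    nb[ok] <- pos[(ncol_i[ok] - 1L) * nr + nrow_i[ok]]
    hit <- which(nb > 0L)
    for (i in hit) {
      ri <- find(i); rj <- find(nb[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n_fg), find, 0L)
  ids <- match(roots, unique(roots))
  lab[fg] <- ids
  attr(lab, "n") <- max(ids)
  lab
}
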