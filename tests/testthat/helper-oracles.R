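# Independent brute-force oracles, deliberately written without reusing any
# package internals: a stack-based 8-connected flood fill and an exhaustive
# connected-components scan. Used to cross-check segmentation exactly.

floodFillOracle <- function(mask, seedRow, seedCol) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!mask[seedRow, seedCol]) return(integer(0))
  visited <- matrix(FALSE, nr, nc)
  visited[seedRow, seedCol] <- TRUE
  stack <- list(c(seedRow, seedCol))
  out <- integer(0)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out <- c(out, (p[2] - 1L) * nr + p[1])
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- p[1] + dr; cc <- p[2] + dc
      if (r >= 1L && r <= nr && cc >= 1L && cc <= nc &&
          mask[r, cc] && !visited[r, cc]) {
        visited[r, cc] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, cc)
      }
    }
  }
  sort(out)
}

# list of sorted linear-index vectors, one per 8-connected component
bruteComponentsOracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    if (mask[r, cc] && !seen[r, cc]) {
      pix <- floodFillOracle(mask, r, cc)
      seen[pix] <- TRUE
      comps[[length(comps) + 1L]] <- pix
    }
  }
  comps
}

# pixel count of the rasterized disk of radius rad centred at (cr, cc)
diskAreaOracle <- function(nr, nc, cr, cc, rad) {
  d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+")
  sum(d2 <= rad^2)
}
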