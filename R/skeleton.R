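# Morphological thinning and skeleton-graph utilities used by the tracer.
# Zhang-Suen thinning is implemented here directly (vectorised over the
# image); the geodesic bookkeeping on the skeleton is delegated to igraph.

#' Shift a matrix so that out[r, c] == m[r - dr, c - dc] (zero fill)
#' @noRd
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Zhang-Suen thinning of a binary matrix to an 8-connected skeleton
#' @noRd
.zhang_suen <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
               c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) .shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        j <- if (i == 8) 1 else i + 1
        (P[[i]] == 0) & (P[[j]] == 1)
      }))
      if (step == 1) {
        c3 <- P[[1]] * P[[3]] * P[[5]] == 0   # P2*P4*P6
        c4 <- P[[3]] * P[[5]] * P[[7]] == 0   # P4*P6*P8
      } else {
        c3 <- P[[1]] * P[[3]] * P[[7]] == 0   # P2*P4*P8
        c4 <- P[[1]] * P[[5]] * P[[7]] == 0   # P2*P6*P8
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Number of 8-neighbours of each skeleton pixel
#' @noRd
.skel_neighbour_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  offs <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
               c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))
  Reduce(`+`, lapply(offs, function(o) .shift_mat(m, o[1], o[2])))
}

#' Build an igraph over skeleton pixels with Euclidean edge weights.
#' Returns NULL when the skeleton has fewer than 2 pixels.
#' @noRd
.skeleton_graph <- function(sk) {
  lin <- which(sk)
  if (length(lin) < 2) return(NULL)
  nr <- nrow(sk)
  id <- integer(length(sk)); id[lin] <- seq_along(lin)
  edges <- list(); wts <- list(); k <- 0
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- .shift_mat(matrix(as.integer(sk), nrow(sk), ncol(sk)), o[1], o[2])
    both <- which(sk & nb == 1L)
    if (!length(both)) next
    src <- both - o[1] - o[2] * nr       # linear index of the shifted-from pixel
    k <- k + 1
    edges[[k]] <- cbind(id[src], id[both])
    wts[[k]] <- rep(sqrt(o[1]^2 + o[2]^2), length(both))
  }
  if (k == 0) return(NULL)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = unlist(wts))
  if (igraph::vcount(g) < length(lin)) {
    g <- igraph::add_vertices(g, length(lin) - igraph::vcount(g))
  }
  list(graph = g, coords = cbind(row = ((lin - 1) %% nr) + 1,
                                 col = ((lin - 1) %/% nr) + 1),
       id_of = id)
}

#' 8-connected component labelling of a binary matrix
#'
#' `EBImage::bwlabel` joins pixels 4-adjacently; puncta and skeleton branches
#' are defined 8-adjacently here, so labelling is done on the pixel adjacency
#' graph instead.
#' @noRd
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lin <- which(mask)
  if (!length(lin)) return(lab)
  if (length(lin) == 1L) { lab[lin] <- 1L; return(lab) }
  sg <- .skeleton_graph(mask)
  if (is.null(sg)) {           # all pixels isolated
    lab[lin] <- seq_along(lin)
    return(lab)
  }
  comp <- igraph::components(sg$graph)
  lab[lin] <- comp$membership
  lab
}
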