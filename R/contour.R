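## 2D contour tracing and chain ordering utilities.

## Moore-neighbour boundary tracing with Jacob's stopping criterion.
## Returns an ordered (closed) cycle of boundary pixel coordinates
## (n x 2 matrix) of the 8-connected object containing `start`
## (default: first foreground pixel in scan order).
.mooreTrace <- function(mask, maxit = 8L * sum(mask) + 16L) {
  stopifnot(any(mask))
  nx <- nrow(mask); ny <- ncol(mask)
  at <- function(i, j) i >= 1 && i <= nx && j >= 1 && j <= ny && mask[i, j]
  ## clockwise 8-neighbourhood starting west
  nb <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1),
              c(0, -1, -1, -1, 0, 1, 1, 1))
  w <- which(mask, arr.ind = TRUE)
  o <- order(w[, 2], w[, 1])   # scan columns, then rows
  s <- w[o[1], ]
  path <- matrix(s, 1, 2)
  ## backtrack: the pixel "above" in scan order is background by choice of s
  bdir <- 3L    # entered from (0,-1), i.e. previous scan position
  cur <- s
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) break
    found <- FALSE
    for (q in 0:7) {
      dir <- (bdir + q) %% 8L + 1L
      ci <- cur[1] + nb[dir, 1]; cj <- cur[2] + nb[dir, 2]
      if (at(ci, cj)) {
        ## new backtrack: the neighbour just before this one (clockwise)
        prev <- (bdir + q - 1L) %% 8L + 1L
        bcell <- c(cur[1] + nb[prev, 1], cur[2] + nb[prev, 2])
        cur <- c(ci, cj)
        ## direction index of the backtrack relative to the new pixel
        dd <- c(bcell[1] - cur[1], bcell[2] - cur[2])
        bdir <- which(nb[, 1] == dd[1] & nb[, 2] == dd[2]) - 1L
        found <- TRUE
        break
      }
    }
    if (!found) break                              # isolated pixel
    if (cur[1] == s[1] && cur[2] == s[2]) break    # closed the cycle
    path <- rbind(path, cur)
  }
  unname(path)
}

## step lengths between consecutive path pixels, in nm. method "vs" uses
## the Vossepoel-Smeulders calibrated chain weights (0.980, 1.406), which
## keep the digital-circle perimeter error near 1%; "chain" uses (1, sqrt2).
.stepLengthsNm <- function(path, sx, method = c("vs", "chain")) {
  method <- match.arg(method)
  if (nrow(path) < 2) return(numeric(0))
  dd <- abs(diff(path))
  diag <- dd[, 1] > 0 & dd[, 2] > 0
  w <- if (method == "vs") c(0.980, 1.406) else c(1, sqrt(2))
  ifelse(diag, w[2], w[1]) * sx
}

## arc step lengths (nm) along a pixel chain, measured on a moving-average
## smoothed polyline. Raw chain-code weights overestimate jagged
## (staircase) chains -- thinning output in particular -- by up to ~35% on
## diagonal stretches; smoothing the coordinates first keeps digital-circle
## perimeters within ~1-2% of truth.
.arcStepsNm <- function(path, sx, window = 5L) {
  n <- nrow(path)
  if (n < 4) return(.stepLengthsNm(path, sx))
  w <- min(window, n - (n + 1) %% 2)
  if (w %% 2 == 0) w <- w - 1L
  if (w >= 3) {
    xs <- as.numeric(stats::filter(path[, 1], rep(1 / w, w), sides = 2))
    ys <- as.numeric(stats::filter(path[, 2], rep(1 / w, w), sides = 2))
    bad <- is.na(xs)
    xs[bad] <- path[bad, 1]
    ys[bad] <- path[bad, 2]
  } else {
    xs <- path[, 1]; ys <- path[, 2]
  }
  sqrt(diff(xs)^2 + diff(ys)^2) * sx
}

## order a 1-pixel-wide skeleton into chains. Returns a list of n x 2
## coordinate matrices; open chains start at an endpoint, closed loops at
## an arbitrary pixel.
.orderChains <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (!nrow(pts)) return(list())
  key <- function(i, j) i + (j - 1) * nrow(mask)
  have <- new.env(hash = TRUE)
  for (r in seq_len(nrow(pts)))
    assign(as.character(key(pts[r, 1], pts[r, 2])), r, envir = have)
  offs <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  neigh <- function(p) {
    out <- NULL
    for (r in seq_len(8)) {
      i <- p[1] + offs[r, 1]; j <- p[2] + offs[r, 2]
      if (i < 1 || i > nrow(mask) || j < 1 || j > ncol(mask)) next
      if (mask[i, j]) out <- rbind(out, c(i, j))
    }
    out
  }
  deg <- vapply(seq_len(nrow(pts)), function(r) {
    nn <- neigh(pts[r, ]); if (is.null(nn)) 0L else nrow(nn)
  }, integer(1))
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  chains <- list()
  walk <- function(startRow) {
    p <- pts[startRow, ]
    chain <- matrix(p, 1, 2)
    visited[p[1], p[2]] <<- TRUE
    repeat {
      nn <- neigh(p)
      if (is.null(nn)) break
      nxt <- NULL
      ## prefer 4-connected continuation to avoid corner cutting
      for (r in seq_len(nrow(nn)))
        if (!visited[nn[r, 1], nn[r, 2]] &&
            sum(abs(nn[r, ] - p)) == 1L) { nxt <- nn[r, ]; break }
      if (is.null(nxt))
        for (r in seq_len(nrow(nn)))
          if (!visited[nn[r, 1], nn[r, 2]]) { nxt <- nn[r, ]; break }
      if (is.null(nxt)) break
      p <- nxt
      visited[p[1], p[2]] <<- TRUE
      chain <- rbind(chain, p)
    }
    chain
  }
  ends <- which(deg <= 1L)
  for (e in ends) {
    p <- pts[e, ]
    if (!visited[p[1], p[2]]) chains[[length(chains) + 1L]] <- walk(e)
  }
  ## remaining pixels belong to closed loops
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    if (!visited[p[1], p[2]]) chains[[length(chains) + 1L]] <- walk(r)
  }
  lapply(chains, unname)
}

## prune dangling skeleton branches shorter than `min_len` pixels:
## segments between a branch point and an endpoint
.pruneSkeleton <- function(mask, min_len = 5L) {
  repeat {
    pts <- which(mask, arr.ind = TRUE)
    if (!nrow(pts)) return(mask)
    degArr <- matrix(0L, nrow(mask), ncol(mask))
    offs <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1),
                  c(0, 0, -1, 1, -1, 1, -1, 1))
    for (r in seq_len(8))
      degArr <- degArr + .shift2(mask, offs[r, 1], offs[r, 2], fill = FALSE)
    deg <- degArr * mask
    branch <- mask & deg >= 3L
    if (!any(branch)) return(mask)
    segs <- .orderChains(mask & !branch)
    removed <- FALSE
    for (sg in segs) {
      if (nrow(sg) >= min_len) next
      ## dangling iff at least one end is not adjacent to a branch point
      endAdj <- function(p) any(branch[
        pmax(1, p[1] - 1):pmin(nrow(mask), p[1] + 1),
        pmax(1, p[2] - 1):pmin(ncol(mask), p[2] + 1)])
      if (!endAdj(sg[1, ]) || !endAdj(sg[nrow(sg), ])) {
        mask[sg] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(mask)
  }
}
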