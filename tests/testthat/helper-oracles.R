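# Independent brute-force oracles used to validate the package's core
# algorithms. These deliberately avoid the implementation's code paths:
# the watershed oracle is a repeated global-argmax simulation, the h-maxima
# oracle recomputes dynamics from threshold level sets, the geodesic oracle is
# all-pairs shortest paths on the pixel graph (igraph), and the matching
# oracle enumerates all assignments.

neighbors8_of <- function(i, nr, nc) {
  r <- (i - 1L) %% nr + 1L
  c <- (i - 1L) %/% nr + 1L
  out <- integer(0)
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) out <- c(out, rr + (cc - 1L) * nr)
  }
  out
}

# Repeatedly assign the globally highest-intensity unlabeled pixel >= th2
# adjacent to a labeled pixel; the label comes from the earliest-labeled
# neighbor. Intended for images with distinct intensities.
oracle_watershed <- function(img, seeds, th2) {
  nr <- nrow(img); nc <- ncol(img); npix <- nr * nc
  lab <- seeds
  tstamp <- rep(Inf, npix)
  frontier <- rep(FALSE, npix)
  step <- 0L
  for (i in which(seeds != 0)) {
    step <- step + 1L
    tstamp[i] <- step
    frontier[neighbors8_of(i, nr, nc)] <- TRUE
  }
  assignable <- as.vector(img) >= th2
  repeat {
    cand <- which(frontier & lab == 0 & assignable)
    if (length(cand) == 0) break
    best <- cand[which.max(img[cand])]
    nb <- neighbors8_of(best, nr, nc)
    nb <- nb[lab[nb] != 0]
    src <- nb[which.min(tstamp[nb])]
    lab[best] <- lab[src]
    step <- step + 1L
    tstamp[best] <- step
    frontier[neighbors8_of(best, nr, nc)] <- TRUE
  }
  lab
}

# Regional maxima of an image with distinct values: strictly greater than all
# 8 neighbors (borders padded with -Inf).
oracle_regional_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  padded <- matrix(-Inf, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- img
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (img > padded[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  which(is_max)
}

# Dynamics of each regional maximum by level-set recomputation: the dynamics
# of a maximum at value v is v minus the highest threshold t at which the
# supra-t component containing it already holds a strictly higher pixel.
oracle_dynamics <- function(img) {
  maxima <- oracle_regional_maxima(img)
  vals <- sort(unique(as.vector(img)))
  vapply(maxima, function(p) {
    v <- img[p]
    if (v == max(img)) return(Inf)
    lev <- vals[vals <= v]
    lo <- 1L; hi <- length(lev)   # predicate monotone: true at low t
    pred <- function(t) {
      comp <- gliascope:::label8(img >= t)
      any(img[comp == comp[p]] > v)
    }
    if (!pred(lev[lo])) return(Inf)
    while (lo < hi) {             # find highest level with predicate TRUE
      mid <- (lo + hi + 1L) %/% 2L
      if (pred(lev[mid])) lo <- mid else hi <- mid - 1L
    }
    v - lev[lo]
  }, numeric(1))
}

oracle_hmax_seed_count <- function(img, h) {
  if (diff(range(img)) == 0) return(0L)
  sum(oracle_dynamics(img) >= h)
}

# All-pairs geodesic diameter on the pixel graph with (1, sqrt 2) weights.
oracle_geodesic_diameter <- function(mask) {
  skip_if_not_installed("igraph")
  idx <- which(mask)
  nr <- nrow(mask)
  pos <- match(seq_along(mask), idx)
  edges <- list(); weights <- c()
  arr <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(arr))) {
    r <- arr[k, 1]; c <- arr[k, 2]
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(mask)) next
      j <- pos[rr + (cc - 1L) * nr]
      if (!is.na(j) && j > k) {
        edges[[length(edges) + 1L]] <- c(k, j)
        weights <- c(weights, if (dr != 0 && dc != 0) sqrt(2) else 1)
      }
    }
  }
  if (length(edges) == 0) return(0)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  igraph::E(g)$weight <- weights
  max(igraph::distances(g))
}

# Exhaustive maximum-cardinality, minimum total squared distance matching.
oracle_matching <- function(a, b, max_dist) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0) return(integer(0))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  allowed <- d2 <= max_dist^2
  best <- rep(NA_integer_, n1); best_card <- -1L; best_cost <- Inf
  rec <- function(i, used, cost, card, asg) {
    if (i > n1) {
      if (card > best_card || (card == best_card && cost < best_cost - 1e-12)) {
        best_card <<- card; best_cost <<- cost; best <<- asg
      }
      return(invisible())
    }
    rec(i + 1L, used, cost, card, c(asg, NA_integer_))
    if (n2 > 0) for (j in seq_len(n2)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + d2[i, j], card + 1L, c(asg, j))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, max(n2, 1L)), 0, 0L, integer(0))
  best
}

matching_cost <- function(asg, a, b) {
  card <- 0L; cost <- 0
  for (i in seq_along(asg)) {
    if (!is.na(asg[i])) {
      card <- card + 1L
      cost <- cost + sum((a[i, ] - b[asg[i], ])^2)
    }
  }
  c(cardinality = card, cost = cost)
}

# Random smooth test image with effectively distinct pixel values.
random_smooth_image <- function(nr, nc, smooth_sigma = 1) {
  img <- matrix(runif(nr * nc), nr, nc)
  if (smooth_sigma > 0)
    img <- gliascope:::as_img_matrix(EBImage::gblur(img, smooth_sigma))
  img
}

# Random connected mask of at most max_px pixels (largest component of a
# thresholded noise field).
random_connected_mask <- function(nr, nc, fill = 0.55, max_px = 600) {
  repeat {
    m <- matrix(runif(nr * nc) < fill, nr, nc)
    lab <- gliascope:::label8(m)
    if (max(lab) == 0) next
    areas <- tabulate(lab[lab > 0])
    big <- which.max(areas)
    if (areas[big] >= 5 && areas[big] <= max_px) return(lab == big)
  }
}

# Overlap-maximizing per-cell IoU between a truth and a predicted label map.
mean_matched_iou <- function(truth, pred) {
  tm <- gliascope:::lab_pixels(truth); pm <- gliascope:::lab_pixels(pred)
  ids <- sort(setdiff(unique(as.vector(tm)), 0L))
  ious <- vapply(ids, function(id) {
    tmask <- tm == id
    ov <- table(pm[tmask])
    ov <- ov[names(ov) != "0"]
    if (length(ov) == 0) return(0)
    best <- as.integer(names(ov)[which.max(ov)])
    pmask <- pm == best
    sum(tmask & pmask) / sum(tmask | pmask)
  }, numeric(1))
  mean(ious)
}
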