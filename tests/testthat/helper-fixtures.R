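# Fixtures and independent oracles shared across the test files.

# A frame with one or more Gaussian blobs on a dark background.
blob_frame <- function(h, w, centers, sigma = 4, amp = 1, background = 0) {
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- matrix(background, h, w)
  for (i in seq_len(nrow(centers)))
    f <- f + amp * exp(-((ys - centers[i, 1])^2 + (xs - centers[i, 2])^2) /
                         (2 * sigma^2))
  f
}

# A hard-edged disk image and mask.
disk_frame <- function(h, w, cy, cx, r, inside = 1, outside = 0) {
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- (ys - cy)^2 + (xs - cx)^2 <= r^2
  f <- matrix(outside, h, w)
  f[m] <- inside
  list(frame = f, mask = m)
}

# Closed boundary polyline of a circle / ellipse, analytic, (y, x) rows.
circle_boundary <- function(cy, cx, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(y = cy - r * sin(th), x = cx + r * cos(th))
}
ellipse_boundary <- function(cy, cx, a, b, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  list(boundary = cbind(y = cy - r * sin(th), x = cx + r * cos(th)),
       theta = th, r = r)
}

# Independent connected-component oracle built on igraph: pixels are nodes,
# neighbor pairs are edges, components come from graph traversal. Returns a
# label matrix (labels arbitrary but consistent).
oracle_label_components <- function(bin, connectivity) {
  bin <- bin != 0
  h <- nrow(bin); w <- ncol(bin)
  idx <- which(bin)
  if (!length(idx)) return(matrix(0L, h, w))
  offs <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  node <- match(seq_len(h * w), idx)  # pixel index -> node id
  ys <- (idx - 1) %% h + 1; xs <- (idx - 1) %/% h + 1
  eparts <- lapply(offs, function(o) {
    ny <- ys + o[1]; nx <- xs + o[2]
    ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= w
    j <- (nx[ok] - 1) * h + ny[ok]
    i <- idx[ok]
    keep <- bin[j] & j > i
    rbind(node[i[keep]], node[j[keep]])
  })
  edges <- as.integer(unlist(eparts))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, h, w)
  lab[idx] <- memb
  lab
}

# Compare two label matrices up to relabeling: identical partitions?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Brute-force minimal-total-distance bipartite matching (<= 6 objects),
# max cardinality first; used as the linking oracle.
oracle_match <- function(from, to, max_disp) {
  n1 <- nrow(from); n2 <- nrow(to)
  d <- sqrt(outer(from[, 1], to[, 1], "-")^2 +
            outer(from[, 2], to[, 2], "-")^2)
  best <- NULL; best_card <- -1L; best_cost <- Inf
  cols <- seq_len(n2)
  # enumerate all injective partial assignments via permutations of padded set
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  padded <- c(cols, rep(NA, n1))
  seen <- new.env()
  for (p in perm(padded)) {
    asg <- p[seq_len(n1)]
    key <- paste(asg, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    ok <- !is.na(asg)
    if (any(duplicated(asg[ok]))) next
    if (any(d[cbind(which(ok), asg[ok])] > max_disp)) next
    card <- sum(ok)
    cost <- sum(d[cbind(which(ok), asg[ok])])
    if (card > best_card || (card == best_card && cost < best_cost)) {
      best <- asg; best_card <- card; best_cost <- cost
    }
  }
  best
}

# Direct-loop Richardson-Lucy reference (independent of the package's FFT
# convolution): O(H W k^2) convolution with reflective boundary.
ref_conv2_reflect <- function(img, k) {
  kh <- (nrow(k) - 1) / 2; kw <- (ncol(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    s <- 0
    for (dy in -kh:kh) for (dx in -kw:kw)
      s <- s + k[dy + kh + 1, dx + kw + 1] *
        img[refl(y - dy, h), refl(x - dx, w)]
    out[y, x] <- s
  }
  out
}
ref_lucy_richardson <- function(d, k, n_iter, eps = 1e-12) {
  kf <- k[nrow(k):1, ncol(k):1, drop = FALSE]
  u <- d
  for (i in seq_len(n_iter)) {
    blur <- ref_conv2_reflect(u, k)
    ratio <- ifelse(blur > eps, d / blur, 1)
    u <- u * ref_conv2_reflect(ratio, kf)
  }
  u
}
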