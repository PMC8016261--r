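# Independent from-definition oracles used to cross-check the package's
# implementations on small inputs. These deliberately take different code
# paths (plain loops, pairwise counts, direct hypergeometric sums) from
# the functions they verify.

# z-score straight from its definition, with explicit loops.
oracle_z <- function(green, red, pos_frac = 0.5, neg_frac = 0.25) {
  gmax <- max(green)
  pos <- c(); neg <- c()
  for (i in seq_along(green)) {
    if (green[i] > pos_frac * gmax) pos <- c(pos, red[i])
    else if (green[i] < neg_frac * gmax) neg <- c(neg, red[i])
  }
  if (length(pos) < 1 || length(neg) < 2) return(NULL)
  mu <- sum(neg) / length(neg)
  s <- sqrt(sum((neg - mu)^2) / (length(neg) - 1))
  srt <- sort(pos)
  k <- length(srt)
  med <- if (k %% 2 == 1) srt[(k + 1) / 2] else (srt[k / 2] + srt[k / 2 + 1]) / 2
  if (s == 0) {
    if (med == mu) return(0) else return(NULL)
  }
  (med - mu) / s
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment of
# the pooled observations (bitmask subsets; U computed by pairwise counts,
# not ranks).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); m <- length(x)
  u_of <- function(xx, yy) {
    u <- 0
    for (a in xx) for (b in yy) u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  u_obs <- u_of(x, y)
  us <- c()
  for (mask in 0:(2^N - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(N - 1))))
    if (sum(sel) != m) next
    us <- c(us, u_of(pooled[sel], pooled[!sel]))
  }
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Two-sided Fisher exact p: sum of hypergeometric probabilities of all
# tables (with the observed margins) no more probable than the observed
# one. The 1 + 1e-7 relative tolerance is the usual guard against ties
# lost to floating point.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Welch two-sample two-sided t-test from its formulas.
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Independent chord search over the same angle grid as place_line: for
# each angle, walk outward from the peak collecting rounded points while
# inside the mask, then sample the segment parametrically and test the
# nucleolus overlap.
oracle_best_chord <- function(nucleus, peak, nucleolus = NULL,
                              angle_step = 1) {
  seg_pts <- function(a, b) {
    n <- max(abs(b - a)) + 1
    t <- seq(0, 1, length.out = n)
    cbind(round(a[1] + t * (b[1] - a[1])), round(a[2] + t * (b[2] - a[2])))
  }
  best <- NULL
  for (ang in seq(0, 180 - angle_step, by = angle_step)) {
    th <- ang * pi / 180
    d <- c(sin(th), cos(th))
    ends <- list()
    for (s in c(-1, 1)) {
      last <- peak; k <- 1
      repeat {
        p <- round(peak + s * k * d)
        if (p[1] < 1 || p[1] > nrow(nucleus) || p[2] < 1 ||
            p[2] > ncol(nucleus) || !nucleus[p[1], p[2]]) break
        last <- p; k <- k + 1
      }
      ends[[length(ends) + 1]] <- last
    }
    pts <- seg_pts(ends[[1]], ends[[2]])
    if (!is.null(nucleolus) && any(nucleolus[cbind(pts[, 1], pts[, 2])]))
      next
    if (nrow(pts) < 10) next
    if (is.null(best) || nrow(pts) > best$n) {
      best <- list(a = ends[[1]], b = ends[[2]], angle = ang, n = nrow(pts))
    }
  }
  best
}

# Minimal profile object bypassing the length->=10 constructor check, for
# pinning hand-computed scoring examples on short vectors.
tiny_profile <- function(green, red) {
  structure(list(position = seq_along(green), green = green, red = red,
                 blue = rep(0, length(green)), cell_id = "tiny",
                 construct = NA_character_, mark = NA_character_,
                 treatment = NA_character_),
            class = "line_profile")
}

disc <- function(dim, center, radius) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}
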