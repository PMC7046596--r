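# Shared fixtures and independent oracle implementations. The oracles here
# deliberately re-implement the algorithms naively (recomputing everything
# each round) and never call into the code paths they check.

rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# random blob mask: a filled ellipse at a random position
random_blob <- function(h, w, rmin = 2, rmax = 5) {
  cr <- runif(1, rmax + 1, h - rmax)
  cc <- runif(1, rmax + 1, w - rmax)
  a <- runif(1, rmin, rmax); b <- runif(1, rmin, rmax)
  th <- runif(1, 0, pi)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  u <- ((g$r - cr) * cos(th) + (g$c - cc) * sin(th)) / a
  v <- (-(g$r - cr) * sin(th) + (g$c - cc) * cos(th)) / b
  matrix(u^2 + v^2 <= 1, h, w)
}

random_mask_set <- function(n_masks, h = 24, w = 24) {
  masks <- lapply(seq_len(n_masks), function(i) {
    m <- random_blob(h, w)
    while (!any(m)) m <- random_blob(h, w)
    scored_mask(m, runif(1), source_id = sample.int(5, 1))
  })
  mask_set(masks, dim = c(h, w))
}

random_instance_map <- function(h = 32, w = 32, n = 4) {
  lab <- matrix(0L, h, w)
  for (k in seq_len(n)) {
    m <- random_blob(h, w)
    lab[m & lab == 0L] <- k
  }
  instance_map(lab)
}

# relabel positive labels by first occurrence in column-major scan, so two
# maps equal up to relabelling compare identical()
canonical_map <- function(lm) {
  v <- as.integer(lm)
  u <- unique(v[v > 0L])
  out <- match(v, u)
  out[is.na(out)] <- 0L
  matrix(as.integer(out), nrow(lm), ncol(lm))
}

# Independent brute-force greedy NMS: naive O(n^2) IOU recomputation each
# round, straight from the stated rule.
oracle_nms_masks <- function(ms, cfg) {
  pool <- unclass(ms)
  iou_m <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 0 else sum(a & b) / u
  }
  D <- list()
  while (length(pool) > 0) {
    sc <- sapply(pool, function(m) m$score)
    ar <- sapply(pool, function(m) sum(m$pixels))
    sr <- sapply(pool, function(m) if (is.na(m$source_id)) Inf else m$source_id)
    best <- order(-sc, -ar, sr, seq_along(pool))[1]
    M <- pool[[best]]
    pool <- pool[-best]
    if (cfg$merge_mode == "merge_union" && length(pool) > 0) {
      i0 <- sapply(pool, function(x) iou_m(M$pixels, x$pixels))
      mg <- which(i0 >= cfg$merge_iou)
      if (length(mg) > 0) {
        for (j in mg) M$pixels <- M$pixels | pool[[j]]$pixels
        pool <- pool[-mg]
      }
    }
    if (length(pool) > 0) {
      i1 <- sapply(pool, function(x) iou_m(M$pixels, x$pixels))
      pool <- pool[!(i1 > cfg$suppress_iou)]
    }
    D <- c(D, list(M))
  }
  mask_set(D, dim = attr(ms, "grid_dim"))
}

# brute-force optimal one-to-one assignment maximising total matched overlap
oracle_best_matching <- function(gt, pred) {
  g <- as.integer(gt); p <- as.integer(pred)
  keep <- g > 0L & p > 0L
  if (!any(keep)) return(0L)
  tab <- table(g[keep], p[keep])
  gl <- rownames(tab); pl <- colnames(tab)
  n <- length(gl); m <- length(pl)
  best <- 0
  # enumerate injective maps from the smaller side into the larger
  if (n <= m) {
    perms <- utils::combn(seq_len(m), n, simplify = FALSE)
    for (cols in perms) {
      for (ord in all_perms(n)) {
        best <- max(best, sum(tab[cbind(seq_len(n), cols[ord])]))
      }
    }
  } else {
    perms <- utils::combn(seq_len(n), m, simplify = FALSE)
    for (rows in perms) {
      for (ord in all_perms(m)) {
        best <- max(best, sum(tab[cbind(rows[ord], seq_len(m))]))
      }
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1L)) {
      out <- c(out, list(c(i, rest[p])))
    }
  }
  out
}

class_of <- function(p_oligo) {
  ifelse(p_oligo >= 0.5, "oligodendroglioma", "astrocytoma")
}
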