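# Independent brute-force oracles, written naively on purpose so they share
# no code path with the implementations they check.

# Maximum-entropy threshold by exhaustive evaluation of all 255 candidate
# split levels with explicit entropy sums.
oracle_entropy_threshold <- function(gray) {
  g <- as.integer(round(gray))
  h <- numeric(256)
  for (v in g) h[v + 1] <- h[v + 1] + 1
  p <- h / length(g)
  best_t <- NA_integer_; best_val <- -Inf
  for (t in 0:254) {
    lo <- p[1:(t + 1)]; hi <- p[(t + 2):256]
    Plo <- sum(lo); Phi <- sum(hi)
    if (Plo == 0 || Phi == 0) next
    ent <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log(q)) }
    val <- ent(lo) + ent(hi)
    if (val > best_val + 1e-12) { best_val <- val; best_t <- t }
  }
  best_t
}

# 8-connected component count by repeated flood fill (queue-based).
oracle_component_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    n <- n + 1L
    queue <- list(c(i, j)); lab[i, j] <- n
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= nrow(mask) && b >= 1 && b <= ncol(mask) &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- n
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  list(n = n, labels = lab)
}

# Small solid-color RGB image builder.
flat_rgb <- function(h, w, rgb) {
  array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3L))
}

# Paint a filled disc of one color onto an RGB array.
paint_disc <- function(img, cr, cc, radius, rgb) {
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2])) {
    if ((i - cr)^2 + (j - cc)^2 <= radius^2) img[i, j, ] <- rgb
  }
  img
}

# A minimal hand-built annotation table: one fragment, customizable
# sections. `sections` is a list of lists with fields area, role and a
# data.frame of follicles (possibly empty).
build_fragment <- function(fragment_id = "frag1", arm = "S1P",
                           condition = "F", sections = list()) {
  rows <- lapply(seq_along(sections), function(k) {
    s <- sections[[k]]
    fol <- s$follicles
    n <- if (is.null(fol)) 0L else length(fol$stage)
    base <- data.frame(fragment_id = fragment_id, arm = arm,
                       condition = condition,
                       section_id = sprintf("%s_s%02d", fragment_id, k),
                       analysis_role = s$role %||% "density",
                       section_area_mm2 = s$area,
                       stringsAsFactors = FALSE)
    if (n == 0L) {
      cbind(base, data.frame(follicle_id = NA_character_, stage = NA_character_,
                             granulosa_disorganized = NA, ooplasm_shrunken = NA,
                             oocyte_pyknotic = NA,
                             ki67_pos_granulosa_count = NA_integer_))
    } else {
      cbind(base[rep(1, n), ],
            data.frame(follicle_id = sprintf("f%03d", seq_len(n)),
                       stage = fol$stage,
                       granulosa_disorganized = fol$gd %||% rep(FALSE, n),
                       ooplasm_shrunken = fol$os %||% rep(FALSE, n),
                       oocyte_pyknotic = fol$op %||% rep(FALSE, n),
                       ki67_pos_granulosa_count = fol$ki %||% rep(NA_integer_, n)))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jaccard overlap of two logical masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)
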