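# Independent brute-force oracles.  Each is written as plainly as possible
# (explicit loops, no shared code with the package internals) so it can
# serve as a reference for the vectorized implementations.

# -- chunking / scoring -------------------------------------------------------

# chunks of one label sequence as "start:end:type" strings (0-based closed)
bf_chunks <- function(labels) {
  out <- character()
  cur_start <- NA; cur_type <- NA
  flush <- function(end) {
    if (!is.na(cur_start)) {
      out[[length(out) + 1L]] <<- paste(cur_start, end, cur_type, sep = ":")
    }
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      flush(i - 2L); cur_start <- NA; cur_type <- NA
    } else {
      role <- substr(lab, 1L, 1L)
      type <- substring(lab, 3L)
      if (role == "B" || is.na(cur_start) || type != cur_type) {
        flush(i - 2L)
        cur_start <- i - 1L
        cur_type <- type
      }
    }
  }
  flush(length(labels) - 1L)
  out
}

# strict scores over a list of sentences, each list(gold=..., pred=...)
bf_score <- function(pairs) {
  gold_all <- character(); pred_all <- character()
  for (s in seq_along(pairs)) {
    g <- bf_chunks(pairs[[s]]$gold)
    p <- bf_chunks(pairs[[s]]$pred)
    if (length(g)) gold_all <- c(gold_all, paste0(s, "@", g))
    if (length(p)) pred_all <- c(pred_all, paste0(s, "@", p))
  }
  correct <- 0L
  for (ch in pred_all) if (ch %in% gold_all) correct <- correct + 1L
  r <- if (length(gold_all)) 100 * correct / length(gold_all) else 0
  p <- if (length(pred_all)) 100 * correct / length(pred_all) else 0
  f <- if (r + p > 0) 2 * r * p / (r + p) else 0
  list(gold = length(gold_all), predicted = length(pred_all),
       correct = correct, recall = r, precision = p, f = f)
}

# -- weighted-vote decoding ---------------------------------------------------

# per-token exhaustive argmax with the documented tie rule: scores over all
# labels, first maximum in alphabet order ("O" last), "O" if every score is 0
bf_decode <- function(outputs, labels, V, F_m) {
  n <- nrow(outputs)
  dec <- character(n)
  for (t in seq_len(n)) {
    scores <- setNames(rep(0, length(labels)), labels)
    for (m in seq_len(ncol(outputs))) {
      c_tm <- outputs[t, m]
      j <- which(labels == c_tm)
      scores[j] <- scores[j] + V[m, j] * F_m[m]
    }
    best <- which(scores == max(scores))[1L]
    dec[t] <- if (scores[best] <= 0) "O" else labels[best]
  }
  dec
}

# -- optimal ensemble fitness for a two-classifier bank ----------------------
#
# Ensemble fitness is piecewise constant in V: a token where the classifiers
# disagree (c1 != c2) is decided by comparing s1 = V[1,c1]*F1 with
# s2 = V[2,c2]*F2 (equal-and-zero -> "O"); an agreement token yields its
# label unless both its weights are zero.  The supremum of the fitness over
# all real V therefore equals the maximum over all realizable comparison
# patterns, i.e. over all assignments of the 2*O score products to either
# zero or distinct positive ranks.  This enumeration is exact, and dominates
# any finite grid over V.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

bf_optimal_fitness <- function(bank) {
  stopifnot(ncol(bank$outputs) == 2L)
  labels <- bank$labels
  n_lab <- length(labels)
  o_idx <- which(labels == "O")
  out1 <- bank$outputs[, 1L]; out2 <- bank$outputs[, 2L]
  agree <- out1 == out2
  ctx <- nervote:::fitness_context(bank)  # scorer validated against bf_score
  ids <- seq_len(2L * n_lab)              # 1..n_lab: s1 labels; rest: s2
  best <- -Inf
  seen <- new.env(parent = emptyenv())
  for (zmask in 0:(2^(2L * n_lab) - 1L)) {
    zero <- as.logical(bitwAnd(zmask, 2L^(ids - 1L)))
    nz <- ids[!zero]
    perms <- if (length(nz)) all_perms(nz) else list(integer())
    for (ord in perms) {
      rank <- rep(0L, 2L * n_lab)
      rank[ord] <- seq_along(ord)           # distinct positive ranks
      s1 <- rank[seq_len(n_lab)]
      s2 <- rank[n_lab + seq_len(n_lab)]
      # decision for each ordered (c1, c2) disagreement pair
      dmat <- matrix(0L, n_lab, n_lab)
      for (c1 in seq_len(n_lab)) for (c2 in seq_len(n_lab)) {
        dmat[c1, c2] <- if (s1[c1] == 0L && s2[c2] == 0L) o_idx
                        else if (s1[c1] > s2[c2]) c1
                        else if (s2[c2] > s1[c1]) c2
                        else min(c1, c2)    # positive tie: earliest label
      }
      agree_dec <- ifelse(s1 + s2 > 0L, seq_len(n_lab), o_idx)
      dec <- integer(length(out1))
      dec[agree] <- agree_dec[out1[agree]]
      dec[!agree] <- dmat[cbind(out1[!agree], out2[!agree])]
      sig <- paste(dec[seq_len(min(4000L, length(dec)))], collapse = "")
      if (!is.null(get0(sig, envir = seen, inherits = FALSE))) next
      assign(sig, TRUE, envir = seen)
      fit <- nervote:::fitness_from_decode(dec, ctx)
      if (fit > best) best <- fit
    }
  }
  best
}

# true coarse grid over V for tiny banks
bf_grid_fitness <- function(bank, step = 0.1) {
  n_cls <- ncol(bank$outputs)
  n_lab <- length(bank$labels)
  ctx <- nervote:::fitness_context(bank)
  grid <- seq(0, 1, by = step)
  len <- n_cls * n_lab
  stopifnot(len <= 6L)
  best <- -Inf
  combos <- as.matrix(expand.grid(rep(list(grid), len)))
  for (i in seq_len(nrow(combos))) {
    f <- compute_fitness(as.numeric(combos[i, ]), bank, ctx)
    if (f > best) best <- f
  }
  best
}
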