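#' GA configuration
#'
#' Defaults follow the standard setup for this ensemble-selection GA:
#' population 100, 50 generations, adaptive crossover/mutation probabilities
#' with `k1 = k3 = 1.0` and `k2 = k4 = 0.5` (Srinivas-Patnaik), Laplacian
#' mutation scale `delta = 0.1`, 5-fold cross-validated fitness.
#'
#' @param population_size number of chromosomes P (>= 2).
#' @param generations number of generations G (>= 1).
#' @param k1,k2,k3,k4 adaptive-probability constants in \[0, 1\].
#' @param delta Laplacian mutation scale (> 0).
#' @param folds cross-validation fold count used when building banks.
#' @param rng_seed integer seed for the whole GA run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 50L,
                      k1 = 1.0, k2 = 0.5, k3 = 1.0, k4 = 0.5,
                      delta = 0.1, folds = 5L, rng_seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            k1 >= 0, k1 <= 1, k2 >= 0, k2 <= 1,
            k3 >= 0, k3 <= 1, k4 >= 0, k4 <= 1, delta > 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 k1 = k1, k2 = k2, k3 = k3, k4 = k4, delta = delta,
                 folds = as.integer(folds),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Initialize a GA population
#'
#' Each chromosome is a real vector of length `n_classifiers * n_labels`
#' (the row-major encoding of the vote-weight matrix V), with every gene
#' drawn i.i.d. uniform on \[0, 1\] from the seeded RNG.
#'
#' @param config a [ga_config()].
#' @param n_classifiers number of base classifiers N.
#' @param n_labels number of output labels O.
#' @return list of `population_size` numeric gene vectors.
#' @export
init_population <- function(config, n_classifiers, n_labels) {
  len <- n_classifiers * n_labels
  with_seed(config$rng_seed, {
    lapply(seq_len(config$population_size), function(i) stats::runif(len))
  })
}

# chromosome genes (length N*O, row-major by classifier) -> weight matrix
genes_to_weights <- function(genes, n_classifiers, labels, classifiers = NULL) {
  V <- matrix(genes, nrow = n_classifiers, ncol = length(labels), byrow = TRUE)
  weight_matrix(V, classifiers = classifiers %||% paste0("C", seq_len(n_classifiers)),
                labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precomputed, chromosome-independent scoring state for fast fitness
# evaluation: per-fold token indices and the gold chunk keys, plus integer
# role/type lookups for the label alphabet.  Chunk keys are packed into one
# double (exact below 2^53) to avoid string building in the inner loop.
fitness_context <- function(predictions) {
  labels <- predictions$labels
  role_of <- match(label_role(labels), c("O", "B", "I")) - 1L  # 0/1/2
  type_of <- match(label_type(labels), c("", sort(unique(label_type(labels)))))
  tokens <- predictions$tokens
  pack <- function(sent, start, end, type) {
    ((sent * 4096 + start) * 4096 + end) * 64 + type
  }
  chunk_keys <- function(sent, pos, role, type) {
    n <- length(role)
    ent <- role != 0L
    if (!any(ent)) return(numeric())
    prev_same <- c(FALSE, sent[-1L] == sent[-n])
    continues <- role == 2L & prev_same &
      c(0L, role[-n]) != 0L & c(0L, type[-n]) == type
    start_flag <- ent & !continues
    cid <- cumsum(start_flag)
    idx <- which(ent)
    cid <- cid[idx]
    last <- c(cid[-1L] != cid[-length(cid)], TRUE)
    first <- !duplicated(cid)
    pack(sent[idx][first], pos[idx][first], pos[idx][last], type[idx][first])
  }
  folds <- lapply(seq_along(predictions$folds), function(f) {
    sel <- which(tokens$fold == f)
    gidx <- match(tokens$gold[sel], labels)
    gk <- chunk_keys(tokens$sentence[sel], tokens$position[sel],
                     role_of[gidx], type_of[gidx])
    list(sel = sel, sent = tokens$sentence[sel], pos = tokens$position[sel],
         gold_keys = gk, n_gold = length(gk))
  })
  list(role_of = role_of, type_of = type_of, chunk_keys = chunk_keys,
       folds = folds)
}

# mean-over-folds strict F (percent) for decoded label indices `dec`
fitness_from_decode <- function(dec, ctx) {
  fold_f <- vapply(ctx$folds, function(fd) {
    d <- dec[fd$sel]
    pk <- ctx$chunk_keys(fd$sent, fd$pos, ctx$role_of[d], ctx$type_of[d])
    correct <- sum(pk %in% fd$gold_keys)
    r <- if (fd$n_gold > 0) 100 * correct / fd$n_gold else 0
    p <- if (length(pk) > 0) 100 * correct / length(pk) else 0
    if (r + p > 0) 2 * r * p / (r + p) else 0
  }, numeric(1L))
  mean(fold_f)
}

#' Cross-validated ensemble fitness of a chromosome
#'
#' Decodes every fold's held-out tokens by weighted voting under the weight
#' matrix encoded in the chromosome and scores each fold with strict
#' matching; the fitness is the arithmetic mean of the per-fold overall
#' F-measures (percent scale).
#'
#' @param genes numeric vector of length N*O (row-major V).
#' @param predictions a `prediction_matrix` from [build_model_bank()] or
#'   [simulate_classifier_outputs()].
#' @param context precomputed scoring state (internal; [run_ga()] builds it
#'   once per run).
#' @return numeric fitness in \[0, 100\].
#' @export
compute_fitness <- function(genes, predictions, context = NULL) {
  n_cls <- ncol(predictions$outputs)
  n_lab <- length(predictions$labels)
  if (length(genes) != n_cls * n_lab) {
    stop(sprintf("chromosome length %d does not match N x O = %d x %d",
                 length(genes), n_cls, n_lab))
  }
  if (is.null(context)) context <- fitness_context(predictions)
  V <- matrix(genes, nrow = n_cls, ncol = n_lab, byrow = TRUE)
  dec <- decode_outputs(predictions$outputs, V, predictions$classifier_F)
  fitness_from_decode(dec, context)
}

#' Roulette-wheel selection
#'
#' Samples one chromosome with probability proportional to fitness; if all
#' fitnesses are zero, uniformly.
#'
#' @param population list of gene vectors.
#' @param fitness numeric vector of non-negative fitnesses.
#' @return the index of the selected chromosome.
#' @export
roulette_select <- function(population, fitness) {
  stopifnot(length(population) >= 1L, all(fitness >= 0))
  if (sum(fitness) == 0) return(sample.int(length(population), 1L))
  sample.int(length(population), 1L, prob = fitness)
}

#' Adaptive crossover probability
#'
#' Srinivas-Patnaik rule: for a pair whose larger fitness is `f_prime`,
#' `mu_c = k1 * (f_max - f_prime) / (f_max - f_avg)` when `f_prime >= f_avg`,
#' else `k3`.  Degenerate populations (`f_max == f_avg`) use `k1`.  Pairs
#' containing the population best are thus protected (`mu_c = 0` at
#' `f_prime = f_max`), while below-average pairs always cross.
#'
#' @param f_max maximum population fitness.
#' @param f_avg mean population fitness.
#' @param f_prime larger fitness of the two solutions to be crossed.
#' @param config a [ga_config()].
#' @return crossover probability in \[0, 1\].
#' @export
adaptive_crossover_prob <- function(f_max, f_avg, f_prime, config = ga_config()) {
  if (f_prime > f_max) stop("f_prime exceeds f_max")
  stopifnot(f_max >= f_avg)
  if (f_prime < f_avg) return(config$k3)
  if (f_max == f_avg) return(config$k1)
  config$k1 * (f_max - f_prime) / (f_max - f_avg)
}

#' Adaptive mutation probability
#'
#' `mu_m = k2 * (f_max - f) / (f_max - f_avg)` when `f >= f_avg`, else `k4`;
#' `k2` when the population is degenerate (`f_max == f_avg`).  The population
#' best is never mutated (`mu_m = 0` at `f = f_max`).
#'
#' @param f_max maximum population fitness.
#' @param f_avg mean population fitness.
#' @param f fitness of the chromosome to be mutated.
#' @param config a [ga_config()].
#' @return mutation probability in \[0, 1\].
#' @export
adaptive_mutation_prob <- function(f_max, f_avg, f, config = ga_config()) {
  if (f > f_max) stop("f exceeds f_max")
  stopifnot(f_max >= f_avg)
  if (f < f_avg) return(config$k4)
  if (f_max == f_avg) return(config$k2)
  config$k2 * (f_max - f) / (f_max - f_avg)
}

#' Single-point crossover
#'
#' With probability `mu_c`, picks one cut point uniformly between positions
#' 1 and len-1 and exchanges the tails; otherwise the offspring are copies of
#' the parents.
#'
#' @param parent_a,parent_b equal-length gene vectors.
#' @param mu_c crossover probability.
#' @return list of two offspring gene vectors.
#' @export
single_point_crossover <- function(parent_a, parent_b, mu_c) {
  if (length(parent_a) != length(parent_b)) stop("parent length mismatch")
  len <- length(parent_a)
  if (len >= 2L && stats::runif(1L) < mu_c) {
    cut <- sample.int(len - 1L, 1L)
    list(c(parent_a[seq_len(cut)], parent_b[(cut + 1L):len]),
         c(parent_b[seq_len(cut)], parent_a[(cut + 1L):len]))
  } else {
    list(parent_a, parent_b)
  }
}

# Laplace(mu, b) sampler via inverse CDF; vectorized over mu.
rlaplace <- function(n, mu = 0, b = 1) {
  u <- stats::runif(n) - 0.5
  mu - b * sign(u) * log1p(-2 * abs(u))
}

#' Laplacian mutation
#'
#' Each gene independently, with probability `mu_m`, is replaced by a draw
#' from a Laplace distribution centered at the old value with scale `delta`,
#' then clamped to \[0, 1\].  The Laplace kernel makes any point of the gene
#' range reachable while concentrating mass near the old value
#' (`E|X - mu| = delta`).
#'
#' @param genes numeric gene vector in \[0, 1\].
#' @param mu_m per-gene mutation probability in \[0, 1\].
#' @param delta Laplace scale (> 0).
#' @return mutated gene vector, still in \[0, 1\].
#' @export
laplacian_mutate <- function(genes, mu_m, delta = 0.1) {
  stopifnot(mu_m >= 0, mu_m <= 1, delta > 0)
  if (mu_m == 0) return(genes)
  hit <- stats::runif(length(genes)) < mu_m
  if (any(hit)) {
    genes[hit] <- pmin(1, pmax(0, rlaplace(sum(hit), genes[hit], delta)))
  }
  genes
}

#' Fit a weighted-vote classifier ensemble by genetic search
#'
#' The fitting function of the package.  Searches the space of per-classifier
#' per-class vote-weight matrices V (genes in \[0, 1\]) for the matrix
#' maximizing cross-validated strict-match F-measure of the weighted-vote
#' ensemble, using roulette-wheel selection, adaptive single-point crossover,
#' adaptive Laplacian mutation, and elitism: the best-ever chromosome is held
#' outside the population and re-injected each generation in place of the
#' current worst, so best fitness never decreases.
#'
#' @param predictions a `prediction_matrix` (see [build_model_bank()],
#'   [simulate_classifier_outputs()]).
#' @param config a [ga_config()].
#' @param injected optional list of gene vectors appended to the initial
#'   population (e.g. degenerate single-classifier chromosomes); off by
#'   default, matching the purely random initialization of the method.
#' @return An object of class `ga_ensemble`: list with `weights` (the best
#'   [weight_matrix()]), `genes`, `fitness` (best CV fitness, percent),
#'   `fitness_trace` (best-so-far per generation, non-decreasing),
#'   `mean_trace`, `classifier_F`, `labels`, `classifier_names`, `config`,
#'   and `evaluations` (number of distinct fitness evaluations).
#' @export
run_ga <- function(predictions, config = ga_config(), injected = NULL) {
  n_cls <- ncol(predictions$outputs)
  n_lab <- length(predictions$labels)
  len <- n_cls * n_lab
  cache <- new.env(parent = emptyenv())
  ctx <- fitness_context(predictions)
  n_eval <- 0L
  fit_of <- function(genes) {
    key <- paste(sprintf("%.17g", genes), collapse = ",")
    v <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(v)) {
      v <- compute_fitness(genes, predictions, ctx)
      n_eval <<- n_eval + 1L
      assign(key, v, envir = cache)
    }
    v
  }
  pop <- init_population(config, n_cls, n_lab)
  if (!is.null(injected)) {
    stopifnot(all(lengths(injected) == len))
    pop <- c(pop, lapply(injected, as.numeric))
  }
  P <- length(pop)
  best_genes <- NULL
  best_fit <- -Inf
  trace <- numeric(config$generations)
  mean_trace <- numeric(config$generations)
  with_seed(config$rng_seed + 1L, {
    for (g in seq_len(config$generations)) {
      fits <- vapply(pop, fit_of, numeric(1L))
      # elite re-injection: best-ever chromosome replaces the current worst
      if (best_fit > -Inf && best_fit > min(fits)) {
        w <- which.min(fits)
        pop[[w]] <- best_genes
        fits[w] <- best_fit
      }
      if (max(fits) > best_fit) {
        best_fit <- max(fits)
        best_genes <- pop[[which.max(fits)]]
      }
      trace[g] <- best_fit
      mean_trace[g] <- mean(fits)
      if (g == config$generations) break
      # adaptive formulas operate on the [0, 1] fitness scale
      f01 <- fits / 100
      f_max <- max(f01); f_avg <- mean(f01)
      nxt <- vector("list", P)
      slot <- 1L
      while (slot <= P) {
        ia <- roulette_select(pop, fits)
        ib <- roulette_select(pop, fits)
        f_prime <- max(f01[ia], f01[ib])
        mu_c <- adaptive_crossover_prob(f_max, f_avg, f_prime, config)
        kids <- single_point_crossover(pop[[ia]], pop[[ib]], mu_c)
        for (ki in 1:2) {
          if (slot > P) break
          # offspring inherit the mutation basis of their originating parent
          f_par <- f01[if (ki == 1L) ia else ib]
          mu_m <- adaptive_mutation_prob(f_max, f_avg, f_par, config)
          nxt[[slot]] <- laplacian_mutate(kids[[ki]], mu_m, config$delta)
          slot <- slot + 1L
        }
      }
      pop <- nxt
    }
  })
  structure(list(
    weights = genes_to_weights(best_genes, n_cls, predictions$labels,
                               predictions$classifier_names),
    genes = best_genes,
    fitness = best_fit,
    fitness_trace = trace,
    mean_trace = mean_trace,
    classifier_F = predictions$classifier_F,
    labels = predictions$labels,
    classifier_names = predictions$classifier_names,
    config = config,
    evaluations = n_eval),
    class = "ga_ensemble")
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ga_ensemble <- function(x, ...) {
  cat(sprintf("<ga_ensemble> %d classifiers x %d labels\n",
              nrow(x$weights), ncol(x$weights)))
  cat(sprintf("  CV fitness (strict F, %%): %.2f after %d generations\n",
              x$fitness, length(x$fitness_trace)))
  cat(sprintf("  best individual F_m: %.2f (%s)\n",
              max(x$classifier_F),
              x$classifier_names[which.max(x$classifier_F)]))
  invisible(x)
}

#' @export
summary.ga_ensemble <- function(object, ...) {
  cat(sprintf("GA weighted-vote ensemble (%d classifiers, %d labels)\n",
              nrow(object$weights), ncol(object$weights)))
  cat(sprintf("  population %d, generations %d, seed %d\n",
              object$config$population_size, object$config$generations,
              object$config$rng_seed))
  cat(sprintf("  CV fitness: %.2f; improvement over best individual: %+.2f\n",
              object$fitness, object$fitness - max(object$classifier_F)))
  cat(sprintf("  distinct fitness evaluations: %d\n", object$evaluations))
  cat("\nVote-weight matrix V (rows: classifiers, columns: labels):\n")
  print(round(unclass(object$weights), 3))
  invisible(object)
}

#' @export
coef.ga_ensemble <- function(object, ...) object$weights

#' @export
plot.ga_ensemble <- function(x, ...) {
  gens <- seq_along(x$fitness_trace)
  graphics::plot(gens, x$fitness_trace, type = "s", lwd = 2,
                 xlab = "generation", ylab = "strict-match F (%)",
                 ylim = range(c(x$fitness_trace, x$mean_trace)), ...)
  graphics::lines(gens, x$mean_trace, lty = 2)
  graphics::abline(h = max(x$classifier_F), col = "grey50", lty = 3)
  graphics::legend("bottomright",
                   legend = c("best-so-far", "population mean",
                              "best individual F_m"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1),
                   col = c("black", "black", "grey50"), bty = "n")
  invisible(x)
}

#' Decode token labels with a fitted ensemble
#'
#' @param object a `ga_ensemble`.
#' @param newdata a `prediction_matrix` (classifier outputs for the tokens to
#'   decode) or a character matrix tokens x classifiers.
#' @param ... unused.
#' @return character vector of decoded labels.
#' @export
predict.ga_ensemble <- function(object, newdata, ...) {
  weighted_vote_decode(newdata, object$weights, object$classifier_F)
}
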