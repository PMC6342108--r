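#' Genetic-algorithm configuration
#'
#' Defaults: population 40, at most 100 generations, stop after 15 generations
#' without improvement, elitism 1.  Shape (`b`) genes are sampled and mutated
#' on the log scale within `b_bounds`; magnitude (`r`) genes within
#' `(1, r_cap]`; categorical resistance values within `cat_bounds`.
#'
#' @param pop_size population size (>= 10).
#' @param max_generations generation cap.
#' @param stagnation generations without improvement before stopping.
#' @param seed integer seed.
#' @param b_bounds shape bounds (positive, increasing).
#' @param r_cap magnitude cap (resistance explored up to this value).
#' @param cat_bounds bounds for categorical resistance values.
#' @param tournament tournament size for selection.
#' @param p_mutate per-gene mutation probability.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, max_generations = 100, stagnation = 15,
                      seed = 1, b_bounds = c(0.01, 5), r_cap = 2500,
                      cat_bounds = c(1, 2500), tournament = 3,
                      p_mutate = 0.25) {
  if (pop_size < 10) stop("population must be >= 10")
  if (b_bounds[1] <= 0 || diff(b_bounds) <= 0) stop("b_bounds must be ordered, > 0")
  if (r_cap <= 1) stop("r_cap must exceed 1")
  structure(list(pop_size = pop_size, max_generations = max_generations,
                 stagnation = stagnation, seed = seed, b_bounds = b_bounds,
                 r_cap = r_cap, cat_bounds = cat_bounds,
                 tournament = tournament, p_mutate = p_mutate),
            class = "ga_config")
}

# Generic real+categorical GA maximizer with elitism 1.
# genes: list of gene descriptors, each list(type = "cat", levels = k) or
# list(type = "log", lo, hi).  fitness: function(chromosome numeric vector).
# Returns list(best, fitness, log = best fitness per generation).
run_ga <- function(genes, fitness, cfg) {
  set.seed(cfg$seed)
  ng <- length(genes)
  rand_gene <- function(gd) {
    if (gd$type == "cat") sample.int(gd$levels, 1)
    else exp(stats::runif(1, log(gd$lo), log(gd$hi)))
  }
  pop <- matrix(replicate(cfg$pop_size, vapply(genes, rand_gene, 1.0)),
                nrow = cfg$pop_size, ncol = ng, byrow = TRUE)
  fit <- apply(pop, 1, fitness)
  best_idx <- which.max(fit)
  best <- pop[best_idx, ]; best_fit <- fit[best_idx]
  log_fit <- best_fit
  stagn <- 0
  for (gen in seq_len(cfg$max_generations)) {
    newpop <- matrix(0, cfg$pop_size, ng)
    newpop[1, ] <- best                      # elitism
    for (i in 2:cfg$pop_size) {
      pick <- function() {
        cand <- sample.int(cfg$pop_size, cfg$tournament)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- numeric(ng)
      for (j in seq_len(ng)) {
        gd <- genes[[j]]
        if (gd$type == "cat") {
          child[j] <- if (stats::runif(1) < 0.5) p1[j] else p2[j]
          if (stats::runif(1) < cfg$p_mutate) child[j] <- sample.int(gd$levels, 1)
        } else {
          # blend crossover on the log scale
          a <- stats::runif(1, -0.25, 1.25)
          v <- a * log(p1[j]) + (1 - a) * log(p2[j])
          if (stats::runif(1) < cfg$p_mutate) {
            v <- v + stats::rnorm(1, 0, 0.25 * (log(gd$hi) - log(gd$lo)))
          }
          child[j] <- exp(min(max(v, log(gd$lo)), log(gd$hi)))
        }
      }
      newpop[i, ] <- child
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit + 1e-10) {
      best_fit <- fit[gen_best]; best <- pop[gen_best, ]; stagn <- 0
    } else {
      stagn <- stagn + 1
    }
    log_fit <- c(log_fit, best_fit)
    if (stagn >= cfg$stagnation) break
  }
  list(best = best, fitness = best_fit, log = log_fit)
}
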