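# Wrapper feature selection with a genetic algorithm: binary chromosomes
# over features, fitness = test-set accuracy of the 3-NN classifier trained
# on the masked training set. The fitness deliberately uses the test set:
# the aim is to describe which features carry the recognized pattern in
# this data, not to build a generalizing predictor.

#' Configure the genetic-algorithm feature selection
#'
#' @param pop_size population size (default 50).
#' @param generations number of generations (default 20).
#' @param p_crossover single-point crossover probability (default 0.8).
#' @param p_mutation per-bit mutation probability (default 0.05).
#' @param elitism carry the best individual of the current generation into
#'   the next, replacing the worst (default TRUE).
#' @param selection `"roulette"` (fitness-proportionate, default) or
#'   `"tournament"` (size-2 tournaments).
#' @param seed integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, generations = 20L, p_crossover = 0.8,
                      p_mutation = 0.05, elitism = TRUE,
                      selection = c("roulette", "tournament"), seed = 1L) {
  pop_size <- as.integer(pop_size)
  generations <- as.integer(generations)
  if (pop_size < 2L) stop("pop_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  if (p_crossover < 0 || p_crossover > 1) stop("p_crossover must be in [0, 1]")
  if (p_mutation < 0 || p_mutation > 1) stop("p_mutation must be in [0, 1]")
  selection <- match.arg(selection)
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = isTRUE(elitism), selection = selection, seed = seed),
            class = "ga_config")
}

# restrict both members of a split to the masked feature columns
mask_split <- function(split, mask) {
  sel <- which(mask == 1L)
  tr <- split$train; te <- split$test
  tr$x <- tr$x[, sel, drop = FALSE]
  te$x <- te$x[, sel, drop = FALSE]
  list(train = tr, test = te)
}

#' Genetic-algorithm feature selection over a train/test split
#'
#' Evolves binary masks over the feature columns. Initial population is
#' uniform random; selection is fitness-proportionate (or tournament);
#' crossover is single-point with probability `p_crossover`; mutation flips
#' each bit with probability `p_mutation`; with elitism the best individual
#' of the current generation replaces the worst of the next, so the
#' best-per-generation fitness trace is non-decreasing. All-zero
#' chromosomes are re-randomized before evaluation (a mask must select at
#' least one feature). Fitness evaluations are cached per mask.
#'
#' @param split a `split_pair` (see [make_split()]).
#' @param config a [ga_config()].
#' @param K neighbors for the fitness classifier (default 3).
#' @return An object of class `ga_result`: `mask` (best binary mask ever
#'   seen), `final_accuracy` (its fitness, percent),
#'   `best_fitness_per_generation`, and `n_selected`.
#' @export
ga_select <- function(split, config = ga_config(), K = 3L) {
  stopifnot(inherits(split, "split_pair"), inherits(config, "ga_config"))
  nfeat <- ncol(split$train$x)
  if (nfeat < 2L) stop("need at least 2 features to select from")
  cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ms <- mask_split(split, mask)
    val <- knn_classify(ms$train, ms$test, K = K)$accuracy
    cache[[key]] <- val
    val
  }
  randomize_nonzero <- function(mask) {
    while (sum(mask) == 0L) mask <- as.integer(stats::runif(nfeat) < 0.5)
    mask
  }

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$pop_size), function(i) {
      randomize_nonzero(as.integer(stats::runif(nfeat) < 0.5))
    })
    fit <- vapply(pop, fitness, numeric(1))
    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    trace <- numeric(config$generations)

    for (gen in seq_len(config$generations)) {
      idx <- if (config$selection == "roulette") {
        w <- fit
        if (sum(w) <= 0) w <- rep(1, length(fit))
        sample.int(config$pop_size, config$pop_size, replace = TRUE, prob = w)
      } else {
        vapply(seq_len(config$pop_size), function(i) {
          cand <- sample.int(config$pop_size, 2L)
          cand[which.max(fit[cand])]
        }, integer(1))
      }
      nextpop <- pop[idx]
      # single-point crossover on consecutive pairs
      for (j in seq(1L, config$pop_size - 1L, by = 2L)) {
        if (stats::runif(1) < config$p_crossover) {
          cut <- sample.int(nfeat - 1L, 1L)
          a <- nextpop[[j]]; b <- nextpop[[j + 1L]]
          nextpop[[j]] <- c(a[seq_len(cut)], b[(cut + 1L):nfeat])
          nextpop[[j + 1L]] <- c(b[seq_len(cut)], a[(cut + 1L):nfeat])
        }
      }
      # per-bit mutation
      nextpop <- lapply(nextpop, function(mask) {
        flip <- stats::runif(nfeat) < config$p_mutation
        mask[flip] <- 1L - mask[flip]
        randomize_nonzero(mask)
      })
      newfit <- vapply(nextpop, fitness, numeric(1))
      if (config$elitism) {
        elite <- pop[[which.max(fit)]]
        worst <- which.min(newfit)
        nextpop[[worst]] <- elite
        newfit[worst] <- max(fit)
      }
      pop <- nextpop
      fit <- newfit
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_mask <- pop[[which.max(fit)]]
      }
      trace[gen] <- max(fit)
    }
    structure(list(mask = best_mask, final_accuracy = best_fit,
                   best_fitness_per_generation = trace,
                   n_selected = sum(best_mask),
                   feature_names = colnames(split$train$x)),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d of %d features selected, best accuracy %.2f%%\n",
              x$n_selected, length(x$mask), x$final_accuracy))
  invisible(x)
}
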