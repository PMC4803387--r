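# Hyperparameter optimization: GA and grid search against CV AUC, with a
# persistent evaluation cache.

#' Gene definitions for one algorithm's search space
#'
#' Default bounds are envelopes of the operating points this family of
#' predictors is reported with: SVM cost in \[0.1, 30\] and sigma in
#' \[0.05, 5\]; NN hidden nodes in \[5, 50\] and learning rate in
#' \[0.01, 5\]; RF trees in \[100, 2500\] and split tries in \[1, 40\];
#' window w odd in \{3, ..., 21\}.
#'
#' @param algorithm `"svm"`, `"nn"` or `"rf"`.
#' @param include_w Whether the window size is a tunable gene (needed when
#'   optimizing over a `pl_corpus`; encoded data has a fixed w).
#' @param bounds Named list of `c(lo, hi)` overrides per gene.
#' @param fixed Named list of parameters pinned to a value and removed from
#'   the genotype.
#' @return Object of class `pl_space`: data frame of gene name, type
#'   (`real`/`int`/`odd`), lo, hi, plus attributes `algorithm` and `fixed`.
#' @export
param_space <- function(algorithm = c("svm", "nn", "rf"), include_w = TRUE,
                        bounds = list(), fixed = list()) {
  algorithm <- match.arg(algorithm)
  def <- switch(algorithm,
    svm = data.frame(name = c("C", "sigma"), type = c("real", "real"),
                     lo = c(0.1, 0.05), hi = c(30, 5)),
    nn = data.frame(name = c("hidden_nodes", "learning_rate"),
                    type = c("int", "real"), lo = c(5, 0.01), hi = c(50, 5)),
    rf = data.frame(name = c("n_trees", "mtry"), type = c("int", "int"),
                    lo = c(100, 1), hi = c(2500, 40))
  )
  if (include_w)
    def <- rbind(def, data.frame(name = "w", type = "odd", lo = 3, hi = 21))
  for (nm in names(bounds)) {
    i <- match(nm, def$name)
    if (is.na(i)) stop("unknown gene in bounds: ", nm, call. = FALSE)
    def$lo[i] <- bounds[[nm]][1]
    def$hi[i] <- bounds[[nm]][2]
  }
  def <- def[!(def$name %in% names(fixed)), , drop = FALSE]
  structure(def, algorithm = algorithm, fixed = fixed, class = c("pl_space",
                                                                 "data.frame"))
}

.gene_draw <- function(type, lo, hi) {
  switch(type,
    real = stats::runif(1, lo, hi),
    int = sample(seq.int(lo, hi), 1),
    odd = sample(seq(lo, hi, by = 2), 1)
  )
}

#' Draw a random genotype from a search space
#'
#' Real genes from a continuous uniform, integer/odd genes from a discrete
#' uniform over the bounds.
#' @param space A `pl_space`.
#' @return Named numeric vector, one gene per tunable parameter.
#' @export
random_genotype <- function(space) {
  g <- vapply(seq_len(nrow(space)),
              function(i) .gene_draw(space$type[i], space$lo[i], space$hi[i]),
              0)
  names(g) <- space$name
  g
}

#' Decode a genotype into hyperparameters
#'
#' Integer genes are rounded, the w gene is snapped to the nearest odd value
#' in bounds, and fixed parameters are merged back in.
#' @param genotype Named numeric vector over the space's genes.
#' @param space A `pl_space`.
#' @param w_default Window size used when w is neither a gene nor fixed
#'   (encoded datasets carry their own w).
#' @return A `pl_params`.
#' @export
decode_genotype <- function(genotype, space, w_default = 9) {
  if (!all(space$name %in% names(genotype)))
    stop("genotype is missing gene(s): ",
         paste(setdiff(space$name, names(genotype)), collapse = ", "),
         call. = FALSE)
  vals <- as.list(attr(space, "fixed"))
  for (i in seq_len(nrow(space))) {
    v <- genotype[[space$name[i]]]
    v <- switch(space$type[i],
                real = v,
                int = as.integer(round(v)),
                odd = { o <- 2 * round((v - 1) / 2) + 1
                        as.integer(min(max(o, space$lo[i]), space$hi[i])) })
    vals[[space$name[i]]] <- v
  }
  if (is.null(vals$w)) vals$w <- w_default
  do.call(hyperparams, c(list(algorithm = attr(space, "algorithm")), vals))
}

.param_key <- function(params) {
  nm <- setdiff(sort(names(unclass(params))), c("algorithm", "kernel_variant"))
  vals <- vapply(nm, function(n) {
    v <- params[[n]]
    if (is.numeric(v) && !is.integer(v)) sprintf("%.4f", v) else as.character(v)
  }, "")
  paste0(params$algorithm, "|", paste(nm, vals, sep = "=", collapse = ";"))
}

#' Persistent evaluation cache
#'
#' Maps a canonical genotype key (fixed field order, reals rounded to 4
#' decimals) to its evaluated fitness, so re-evaluating a genotype never
#' retrains. `cache_trainings()` counts actual (non-cached) evaluations.
#'
#' @return An empty `pl_cache`.
#' @export
eval_cache <- function() {
  e <- new.env(parent = emptyenv())
  assign(".trainings", 0L, envir = e)
  structure(list(env = e), class = "pl_cache")
}

#' @rdname eval_cache
#' @param cache A `pl_cache`.
#' @export
cache_size <- function(cache) length(ls(cache$env))

#' @rdname eval_cache
#' @export
cache_trainings <- function(cache) get(".trainings", envir = cache$env)

#' @rdname eval_cache
#' @param path File path for the TSV serialization.
#' @export
save_cache <- function(cache, path) {
  keys <- setdiff(ls(cache$env), ".trainings")
  tab <- data.frame(
    key = keys,
    auc = vapply(keys, function(k) get(k, envir = cache$env)$auc, 0),
    se = vapply(keys, function(k) get(k, envir = cache$env)$se, 0)
  )
  tab <- tab[order(tab$key), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname eval_cache
#' @export
load_cache <- function(path) {
  cache <- eval_cache()
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab)))
    assign(tab$key[i], list(auc = tab$auc[i], se = tab$se[i]),
           envir = cache$env)
  cache
}

# Evaluations reset the RNG internally (seeded folds/training); callers that
# maintain their own random stream wrap them with this.
.preserving_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) st <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", st, envir = globalenv()))
  expr
}

#' Cross-validated fitness of a genotype
#'
#' Decodes the genotype (re-windowing corpus features at its w), runs seeded
#' stratified k-fold cross-validation, and returns the mean held-out AUC
#' with its standard error across folds. Results are memoized in the cache;
#' a repeated genotype is a lookup, never a retraining. Fold assignment
#' depends only on (labels, folds, seed), so every genotype in one run is
#' scored on identical folds.
#'
#' @param genotype Named numeric vector (see [random_genotype()]).
#' @param data A `pl_corpus` or `pl_dataset`.
#' @param space A `pl_space`.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @param cache Optional `pl_cache`.
#' @return List with `auc` (mean CV AUC), `se` (sd across folds / sqrt(k)),
#'   `params` and `cached` flag.
#' @export
fitness <- function(genotype, data, space, folds = 5, seed = 1,
                    cache = NULL) {
  params <- decode_genotype(genotype, space,
                            w_default = if (inherits(data, "pl_dataset"))
                              data$w else 9)
  key <- .param_key(params)
  if (!is.null(cache) && exists(key, envir = cache$env)) {
    hit <- get(key, envir = cache$env)
    return(list(auc = hit$auc, se = hit$se, params = params, cached = TRUE))
  }
  dataset <- as_dataset(data, params$w)
  rep <- cross_validate(dataset, params, folds = folds, seed = seed)
  auc <- mean(rep$per_fold$auc)
  se <- stats::sd(rep$per_fold$auc) / sqrt(nrow(rep$per_fold))
  if (!is.null(cache)) {
    assign(key, list(auc = auc, se = se), envir = cache$env)
    assign(".trainings", cache_trainings(cache) + 1L, envir = cache$env)
  }
  list(auc = auc, se = se, params = params, cached = FALSE)
}

#' Genetic-algorithm hyperparameter search
#'
#' Generational GA with tournament selection (size 2), single-point
#' crossover, per-gene point mutation (uniform redraw within bounds) and
#' elitism of one, optimizing mean cross-validated AUC. The published
#' operating configuration is 100 generations, 20 individuals, mutation rate
#' 0.05 and crossover rate 0.8; scale down for desk-size problems.
#'
#' @param data A `pl_corpus` or `pl_dataset`.
#' @param algorithm `"svm"`, `"nn"` or `"rf"`.
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param generations,pop,p_mut,p_cross GA constants.
#' @param folds CV folds per fitness evaluation.
#' @param space Optional `pl_space` (default [param_space()] for the
#'   algorithm, with w tunable iff `data` is a corpus).
#' @param cache Optional `pl_cache`, shared across calls.
#' @param tournament Tournament size.
#' @return List with `best` (genotype, params, fitness, se), `trace` (one
#'   row per generation: best-so-far genes, mean_auc, se_auc, runtime_s)
#'   and `cache`.
#' @export
run_ga <- function(data, algorithm = c("svm", "nn", "rf"), seed = 1,
                   generations = 100, pop = 20, p_mut = 0.05, p_cross = 0.8,
                   folds = 5, space = NULL, cache = NULL, tournament = 2) {
  algorithm <- match.arg(algorithm)
  if (is.null(space))
    space <- param_space(algorithm, include_w = inherits(data, "pl_corpus"))
  if (is.null(cache)) cache <- eval_cache()
  stopifnot(pop >= 2)
  set.seed(as.integer(seed))
  t0 <- Sys.time()

  population <- replicate(pop, random_genotype(space), simplify = FALSE)
  evaluate <- function(g) .preserving_rng(
    fitness(g, data, space, folds = folds, seed = seed, cache = cache))

  fits <- vapply(population, function(g) evaluate(g)$auc, 0)
  best_i <- which.max(fits)
  best <- list(genotype = population[[best_i]], fitness = fits[best_i])
  trace <- list(.trace_row(0, best, space, data, folds, seed, cache, t0))

  g_count <- nrow(space)
  for (gen in seq_len(generations)) {
    new_pop <- list(best$genotype) # elitism of 1
    while (length(new_pop) < pop) {
      pick <- function() {
        idx <- sample.int(pop, tournament, replace = TRUE)
        population[[idx[which.max(fits[idx])]]]
      }
      p1 <- pick(); p2 <- pick()
      child <- p1
      if (g_count > 1 && stats::runif(1) < p_cross) {
        cut <- sample.int(g_count - 1, 1)
        child <- c(p1[seq_len(cut)], p2[(cut + 1):g_count])
      }
      for (i in seq_len(g_count)) {
        if (stats::runif(1) < p_mut)
          child[i] <- .gene_draw(space$type[i], space$lo[i], space$hi[i])
      }
      new_pop[[length(new_pop) + 1]] <- child
    }
    population <- new_pop
    fits <- vapply(population, function(g) evaluate(g)$auc, 0)
    gi <- which.max(fits)
    if (fits[gi] > best$fitness)
      best <- list(genotype = population[[gi]], fitness = fits[gi])
    trace[[length(trace) + 1]] <-
      .trace_row(gen, best, space, data, folds, seed, cache, t0)
  }
  bf <- .preserving_rng(fitness(best$genotype, data, space, folds = folds,
                                seed = seed, cache = cache))
  list(best = list(genotype = best$genotype, params = bf$params,
                   fitness = bf$auc, se = bf$se),
       trace = do.call(rbind, trace), cache = cache)
}

.trace_row <- function(gen, best, space, data, folds, seed, cache, t0) {
  bf <- .preserving_rng(fitness(best$genotype, data, space, folds = folds,
                                seed = seed, cache = cache))
  genes <- as.list(best$genotype)
  names(genes) <- paste0("gene_", names(genes))
  cbind(data.frame(generation = gen,
                   runtime_s = round(as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs")), 3)),
        as.data.frame(genes),
        data.frame(mean_auc = bf$auc, se_auc = bf$se))
}

#' Exhaustive grid search over hyperparameter values
#'
#' Evaluates every Cartesian combination of the supplied per-parameter value
#' lists through the same cached CV fitness as the GA, and returns the best
#' cell. Ties are broken by smaller w, then lexicographic gene order.
#'
#' @param data A `pl_corpus` or `pl_dataset`.
#' @param algorithm `"svm"`, `"nn"` or `"rf"`.
#' @param grid Named list of value vectors, one entry per tunable gene of
#'   the space.
#' @param seed Integer seed.
#' @param folds CV folds.
#' @param space Optional `pl_space`.
#' @param cache Optional `pl_cache`.
#' @return List with `best` (genotype, params, fitness, se), `table` (every
#'   evaluated cell with mean_auc, se_auc, cached flag) and `cache`.
#' @export
run_grid <- function(data, algorithm = c("svm", "nn", "rf"), grid, seed = 1,
                     folds = 5, space = NULL, cache = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(space))
    space <- param_space(algorithm, include_w = inherits(data, "pl_corpus"))
  if (is.null(cache)) cache <- eval_cache()
  if (!setequal(names(grid), space$name))
    stop("grid axes must match the space's genes: ",
         paste(space$name, collapse = ", "), call. = FALSE)
  if (any(!lengths(grid)))
    stop("empty grid axis: ",
         paste(names(grid)[!lengths(grid)], collapse = ", "), call. = FALSE)
  cells <- expand.grid(grid[space$name], KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    g <- as.numeric(cells[i, ])
    names(g) <- space$name
    f <- fitness(g, data, space, folds = folds, seed = seed, cache = cache)
    rows[[i]] <- cbind(cells[i, , drop = FALSE],
                       data.frame(mean_auc = f$auc, se_auc = f$se,
                                  cached = f$cached))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- do.call(order, c(list(-tab$mean_auc),
                          if ("w" %in% names(tab)) list(tab$w),
                          lapply(sort(setdiff(space$name, "w")),
                                 function(n) tab[[n]])))
  bi <- ord[1]
  g <- as.numeric(cells[bi, ])
  names(g) <- space$name
  bf <- fitness(g, data, space, folds = folds, seed = seed, cache = cache)
  list(best = list(genotype = g, params = bf$params, fitness = bf$auc,
                   se = bf$se),
       table = tab, cache = cache)
}

#' Write a GA trace (or grid table) as TSV
#' @param trace Data frame from [run_ga()] or [run_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
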