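# Brute-force main/total-effect oracle: explicit nested iteration over level
# combinations, sharing no code with the package implementation. Collapses
# replicate rows to cell means first (population variances throughout).
oracle_indices <- function(df, factors, response = "y") {
  levels_of <- lapply(factors, function(f) sort(unique(df[[f]])))
  names(levels_of) <- factors
  cells <- expand.grid(levels_of, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cmeans <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(df))
    for (f in factors) sel <- sel & df[[f]] == cells[[f]][i]
    cmeans[i] <- mean(df[[response]][sel])
  }
  pvar <- function(x) mean((x - mean(x))^2)
  v_tot <- pvar(cmeans)
  me <- ts <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    lev <- levels_of[[f]]
    level_means <- numeric(length(lev))
    for (j in seq_along(lev)) {
      level_means[j] <- mean(cmeans[cells[[f]] == lev[j]])
    }
    me[f] <- pvar(level_means) / v_tot
    others <- setdiff(factors, f)
    key <- do.call(paste, c(cells[others], sep = "\r"))
    ukey <- unique(key)
    comp_means <- numeric(length(ukey))
    for (j in seq_along(ukey)) {
      comp_means[j] <- mean(cmeans[key == ukey[j]])
    }
    ts[f] <- 1 - pvar(comp_means) / v_tot
  }
  list(me = me, ts = ts)
}

# random balanced factorial over 4 factors with 2-5 levels each
random_factorial <- function(seed) {
  set.seed(seed)
  n_levels <- sample(2:5, 4, replace = TRUE)
  grid <- expand.grid(lapply(n_levels, function(k) paste0("l", seq_len(k))),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- paste0("f", 1:4)
  grid$y <- rnorm(nrow(grid))
  grid
}
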