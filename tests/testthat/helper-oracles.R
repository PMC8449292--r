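# Independent brute-force oracles used to cross-check the package's
# implementations. These share no code with the implementation paths they
# verify.

# presence-fraction scoring by exhaustive n-gram scan: for every lexicon
# term, slide a window of the term's length over the document tokens
oracle_score <- function(tokens, lexicon) {
  domains <- unique(lexicon$domain)
  out <- setNames(numeric(length(domains)), domains)
  for (d in domains) {
    terms <- lexicon$term[lexicon$domain == d]
    matched <- 0L
    for (tm in terms) {
      tt <- strsplit(tm, " ", fixed = TRUE)[[1]]
      k <- length(tt)
      hit <- FALSE
      if (length(tokens) >= k) {
        for (s in seq_len(length(tokens) - k + 1L)) {
          if (identical(tokens[s:(s + k - 1L)], tt)) { hit <- TRUE; break }
        }
      }
      matched <- matched + as.integer(hit)
    }
    out[[d]] <- matched / length(terms)
  }
  out
}

# closed-form OLS via the normal equations
oracle_ols <- function(X, y) {
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# one-binary-predictor logistic MLE: the cross-product odds ratio of the
# 2x2 outcome-by-exposure table
oracle_or_2x2 <- function(y, x) {
  a <- sum(y == 1 & x == 1); b <- sum(y == 0 & x == 1)
  c_ <- sum(y == 1 & x == 0); d <- sum(y == 0 & x == 0)
  (a * d) / (b * c_)
}

# Efron partial log-likelihood for a single covariate with all events
# observed; beta found by grid search
oracle_cox_efron_loglik <- function(time, x, beta) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  ll <- 0
  for (t_j in unique(time)) {
    d_idx <- which(time == t_j)
    r_idx <- which(time >= t_j)
    dj <- length(d_idx)
    sum_d <- sum(exp(beta * x[d_idx]))
    sum_r <- sum(exp(beta * x[r_idx]))
    ll <- ll + beta * sum(x[d_idx])
    for (l in seq_len(dj) - 1L) {
      ll <- ll - log(sum_r - (l / dj) * sum_d)
    }
  }
  ll
}

oracle_cox_efron_beta <- function(time, x, grid = seq(-5, 5, by = 0.001)) {
  ll <- vapply(grid, function(b) oracle_cox_efron_loglik(time, x, b),
               numeric(1))
  grid[which.max(ll)]
}

# randomized fixtures ---------------------------------------------------

random_vocab <- function(n, prefix = "w") paste0(prefix, seq_len(n))

random_lexicon <- function(n_domains = 3, terms_per_domain = 5,
                           phrase_frac = 0.3, vocab = random_vocab(60)) {
  n <- n_domains * terms_per_domain
  if (n > length(vocab)) {
    vocab <- c(vocab, random_vocab(n - length(vocab), prefix = "extra"))
  }
  words <- sample(vocab, n)
  phr <- runif(n) < phrase_frac
  words[phr] <- paste(words[phr], sample(vocab, sum(phr), replace = TRUE))
  as_lexicon(tibble::tibble(
    domain = rep(paste0("d", seq_len(n_domains)), each = terms_per_domain),
    term = words
  ), quiet = TRUE)
}

random_tokens <- function(len, vocab = random_vocab(60)) {
  sample(vocab, len, replace = TRUE)
}

# minimal valid cohort rows for schema tests
make_cohort <- function(n = 6, diagnosis = "depression", los = NULL,
                        patient_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    patient_id = patient_id %||% sprintf("P%03d", seq_len(n)),
    admission_id = sprintf("A%03d", seq_len(n)),
    diagnosis = rep_len(diagnosis, n),
    age = sample(18:80, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    los_days = los %||% runif(n, 1, 20),
    cci = sample(0:3, n, replace = TRUE),
    htn = sample(0:1, n, replace = TRUE),
    dm = sample(0:1, n, replace = TRUE),
    stroke = 0, renal = 0, pneumonia = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

diagnosis_levels_for_test <- function() {
  c("depression", "schizophrenia", "bipolar_disorder")
}
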