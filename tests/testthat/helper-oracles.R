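# Independent oracles used across tests. Deliberately naive implementations
# that share no code with the package internals.

# Lempel-Ziv 1976 production parsing by exhaustive substring search: the next
# word ends at the first position whose word is not a substring of everything
# before it.
lz76_oracle <- function(x) {
  str <- paste(x, collapse = "")
  n <- nchar(str)
  c <- 0; l <- 1
  while (l <= n) {
    j <- l
    repeat {
      w <- substr(str, l, j)
      if (!grepl(w, substr(str, 1, j - 1), fixed = TRUE)) break
      if (j == n) break
      j <- j + 1
    }
    c <- c + 1
    l <- j + 1
  }
  as.integer(c)
}

# Brute-force STTC: proportions from a full distance matrix, tiled time from
# explicit sort-and-merge interval arithmetic.
sttc_oracle <- function(a, b, dt, t_range) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  frac_near <- function(x, y) {
    mean(apply(abs(outer(x, y, `-`)), 1, min) <= dt)
  }
  tiled <- function(x) {
    iv <- cbind(pmax(x - dt, t_range[1]), pmin(x + dt, t_range[2]))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    total <- 0; cur <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= cur[2]) {
        cur[2] <- max(cur[2], iv[i, 2])
      } else {
        total <- total + (cur[2] - cur[1]); cur <- iv[i, ]
      }
    }
    (total + cur[2] - cur[1]) / (t_range[2] - t_range[1])
  }
  pa <- frac_near(a, b); pb <- frac_near(b, a)
  ta <- tiled(a); tb <- tiled(b)
  term <- function(p, tt) if (p == 1 && tt == 1) 0 else (p - tt) / (1 - p * tt)
  0.5 * (term(pa, tb) + term(pb, ta))
}

# Naive multivariate SPIKE synchronization: per-spike double loop over all
# partner trains, adaptive window = half the minimum of the four surrounding
# inter-spike intervals (edge ISIs ignored).
spike_sync_reference <- function(trains) {
  trains <- Filter(length, trains)
  m <- length(trains)
  if (m < 2) return(NA_real_)
  isi_around <- function(tr, k) {
    out <- c(Inf, Inf)
    if (k > 1) out[1] <- tr[k] - tr[k - 1]
    if (k < length(tr)) out[2] <- tr[k + 1] - tr[k]
    out
  }
  num <- 0; den <- 0
  for (i in seq_len(m)) {
    for (k in seq_along(trains[[i]])) {
      t_k <- trains[[i]][k]
      for (j in seq_len(m)[-i]) {
        nn <- which.min(abs(trains[[j]] - t_k))
        d <- abs(trains[[j]][nn] - t_k)
        tau <- min(c(isi_around(trains[[i]], k),
                     isi_around(trains[[j]], nn))) / 2
        num <- num + (d < tau)
      }
      den <- den + (m - 1)
    }
  }
  num / den
}

# Poisson spike train on [0, dur)
poisson_train <- function(rate, dur) {
  n <- stats::rpois(1, rate * dur)
  unique(sort(stats::runif(n, 0, dur)))
}

# small spike-train-set fixture with given per-channel rates
poisson_set <- function(rates, dur) {
  spike_train_set(lapply(rates, poisson_train, dur = dur), 0, dur)
}
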