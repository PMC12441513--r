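# Shared test helpers: quick spectrum construction, an exhaustive
# modified-cosine matcher used as the independent oracle for the greedy
# implementation, and small compound rows for the generator.

spec <- function(mz, intensity = rep(100, length(mz)), precursor = 500,
                 polarity = "negative", id = "s", rt = 5) {
  new_spectrum(id = id, precursor_mz = precursor, polarity = polarity,
               rt = rt, mz = mz, intensity = intensity)
}

# Exhaustive-optimal modified cosine: enumerates every one-to-one matching
# over the candidate pairs (direct or precursor-shifted) and returns the
# maximum score ratio. Independent of the greedy implementation.
brute_modified_cosine <- function(a, b, fragment_tol = 0.02) {
  wa <- sqrt(a$intensity); wb <- sqrt(b$intensity)
  na <- sqrt(sum(wa^2)); nb <- sqrt(sum(wb^2))
  if (na == 0 || nb == 0) return(0)
  shift <- b$precursor_mz - a$precursor_mz
  cand <- list()
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      if (abs(b$mz[j] - a$mz[i]) <= fragment_tol ||
          abs(b$mz[j] - a$mz[i] - shift) <= fragment_tol) {
        cand[[length(cand) + 1L]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (length(cand) == 0) return(0)
  best <- 0
  recurse <- function(k, used_i, used_j, total) {
    if (total > best) best <<- total
    if (k > length(cand)) return()
    # upper bound prune: remaining candidates summed
    rest <- sum(vapply(cand[k:length(cand)], `[[`, numeric(1), 3))
    if (total + rest <= best) return()
    p <- cand[[k]]
    if (!(p[1] %in% used_i) && !(p[2] %in% used_j)) {
      recurse(k + 1L, c(used_i, p[1]), c(used_j, p[2]), total + p[3])
    }
    recurse(k + 1L, used_i, used_j, total)
  }
  recurse(1L, integer(0), integer(0), 0)
  min(1, best / (na * nb))
}

compound_row <- function(id, formula, adduct, class, rt = 5,
                         name = id) {
  data.frame(id = id, rt = rt, name = name, formula = formula,
             adduct = adduct, class = class, stringsAsFactors = FALSE)
}

# random formula over CHNOS for property tests
random_formula <- function() {
  n <- c(C = sample(1:30, 1), H = sample(1:40, 1), N = sample(0:3, 1),
         O = sample(0:15, 1), S = sample(0:1, 1))
  n <- n[n > 0]
  paste0(names(n), n, collapse = "")
}
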