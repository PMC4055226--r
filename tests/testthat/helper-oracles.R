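# Independent brute-force Dempster-Shafer machinery used as a test oracle.
# Masses live in a plain numeric vector indexed by subset bitmask (1..2^n-1),
# combined by direct enumeration of all mask pairs — no shared code with the
# package implementation.

mask_of <- function(labels, frame) {
  sum(2^(match(labels, frame) - 1L))
}

labels_of <- function(mask, frame) {
  frame[bitwAnd(mask, 2^(seq_along(frame) - 1L)) > 0]
}

# mass_function -> bitmask vector
bf_vec <- function(m) {
  n <- length(m$frame)
  v <- numeric(2^n - 1L)
  for (k in seq_along(m$focal)) {
    v[mask_of(m$focal[[k]], m$frame)] <- v[mask_of(m$focal[[k]], m$frame)] +
      m$masses[[k]]
  }
  v
}

# bitmask vector -> mass_function
bf_unvec <- function(v, frame) {
  keep <- which(v > 0)
  mass_function(frame, lapply(keep, labels_of, frame = frame), v[keep])
}

bf_combine <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  out <- numeric(length(v1))
  conflict <- 0
  for (a in which(v1 > 0)) {
    for (b in which(v2 > 0)) {
      inter <- bitwAnd(a, b)
      p <- v1[a] * v2[b]
      if (inter == 0L) conflict <- conflict + p
      else out[inter] <- out[inter] + p
    }
  }
  list(masses = out / (1 - conflict), conflict = conflict)
}

bf_belief <- function(v, mask) {
  sum(v[which(bitwAnd(seq_along(v), mask) == seq_along(v))])
}

# random singleton+Theta mass function on a frame
random_singleton_mass <- function(frame) {
  w <- stats::runif(length(frame) + 1L)
  w <- w / sum(w)
  singleton_mass_function(frame, stats::setNames(w[seq_along(frame)], frame))
}

# random mass function with arbitrary non-empty focal subsets
random_general_mass <- function(frame, n_focal = 4L) {
  masks <- sample(seq_len(2^length(frame) - 1L), n_focal, replace = TRUE)
  w <- stats::runif(n_focal)
  v <- numeric(2^length(frame) - 1L)
  for (k in seq_len(n_focal)) v[masks[k]] <- v[masks[k]] + w[k]
  bf_unvec(v / sum(v), frame)
}

fixture_fss <- function(name) {
  read_fss(system.file("extdata", paste0(name, ".csv"), package = "greysoft"))
}

# Table 7 restricted to the observed symptoms, AND Table 8 (the medical
# decision table)
medical_fss <- function() {
  and_product(select_parameters(fixture_fss("table7"), c("e1", "e2", "e4")),
              fixture_fss("table8"))
}
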