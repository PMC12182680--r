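# Independent rule transcriptions used as oracles. These deliberately use
# plain per-pixel loops and spell out every formula, so they share no code
# path with the vectorised implementations they check.

# cover fusion criteria, transcribed literally:
# (1) two products agree on a forest type -> that type;
# (2) discrepancies -> rank-1 if it reports forest;
# (3) rank-1 non-forest -> rank-2 if forest;
# (4) rank-1 and rank-2 non-forest -> rank-3.
fuse_cover_oracle1 <- function(c1, c2, c3, nf = 0L) {
  if (c1 == c2 && c1 != nf) return(c1)
  if (c1 == c3 && c1 != nf) return(c1)
  if (c2 == c3 && c2 != nf) return(c2)
  if (c1 != nf) return(c1)
  if (c2 != nf) return(c2)
  c3
}

# growth families spelled out
growth_oracle <- function(family, cf, t) {
  if (family == "MM") cf[["mu"]] * t / (cf[["k"]] + t)
  else if (family == "MO") cf[["mu"]] * (1 - cf[["c"]] * exp(-cf[["alpha"]] * t))
  else cf[["mu"]] / (1 + cf[["c"]] * exp(-cf[["alpha"]] * t))
}

agbc_oracle <- function(fit, t, mat, map) {
  cf <- fit$coefficients
  max(growth_oracle(fit$family, cf, t) +
        cf[["a"]] * mat + cf[["b"]] * map + cf[["d"]], 0)
}

# literal per-pixel transcription of the nature-scenario rules
nature_oracle <- function(state, suit, mtss, climate_now, climate_future,
                          fits, F, spec) {
  codes <- sort(as.integer(names(suit)))
  N <- spec$N
  half <- if (spec$round_ages) round(N / 2) else N / 2
  g <- state$geom
  type <- matrix(0L, g$nrow, g$ncol)
  age <- matrix(NA_real_, g$nrow, g$ncol)
  c_age <- matrix(0, g$nrow, g$ncol)
  c_climate <- matrix(0, g$nrow, g$ncol)
  c_co2 <- matrix(0, g$nrow, g$ncol)
  status <- matrix(0L, g$nrow, g$ncol)
  for (r in seq_len(g$nrow)) for (cc in seq_len(g$ncol)) {
    A <- state$type[r, cc]
    if (A == 0L) next
    t0 <- state$age[r, cc]
    if (suit[[as.character(A)]][r, cc] > mtss[[as.character(A)]]) {
      B <- A; tnew <- t0 + N; st <- 1L
    } else {
      B <- NA_integer_; bp <- -Inf
      for (k in setdiff(codes, A)) {
        pk <- suit[[as.character(k)]][r, cc]
        if (pk > mtss[[as.character(k)]] && pk > bp) { B <- k; bp <- pk }
      }
      if (is.na(B)) { status[r, cc] <- 3L; next }
      tnew <- half; st <- 2L
    }
    fit <- fits[[as.character(B)]]
    ca <- agbc_oracle(fit, tnew, climate_now$mat[r, cc],
                      climate_now$map[r, cc])
    cac <- agbc_oracle(fit, tnew, climate_future$mat[r, cc],
                       climate_future$map[r, cc])
    type[r, cc] <- B
    age[r, cc] <- tnew
    c_age[r, cc] <- ca
    c_climate[r, cc] <- cac - ca
    c_co2[r, cc] <- (F - 1) * ca
    status[r, cc] <- st
  }
  list(type = type, age = age, c_age = c_age, c_climate = c_climate,
       c_co2 = c_co2, c_total = c_age + c_climate + c_co2, status = status)
}

# literal transcription of the afforestation allocation rules
afforest_oracle <- function(state_nature, suit, mtss, area_needed_mha,
                            climate_now, climate_future, fits, F, spec,
                            seed) {
  codes <- sort(as.integer(names(suit)))
  g <- state_nature$geom
  half <- if (spec$round_ages) round(spec$N / 2) else spec$N / 2
  areas <- cell_area_matrix(g) / 1e6
  cand <- integer(0)
  for (i in seq_len(g$nrow * g$ncol)) {
    if (state_nature$type[i] != 0L) next
    any_ok <- FALSE
    for (k in codes)
      if (suit[[as.character(k)]][i] > mtss[[as.character(k)]]) any_ok <- TRUE
    if (any_ok) cand <- c(cand, i)
  }
  out <- state_nature
  if (area_needed_mha == 0 || length(cand) == 0) return(out)
  set.seed(seed)
  ord <- sample(cand)
  tot <- 0
  for (i in ord) {
    if (tot >= area_needed_mha) break
    B <- NA_integer_; bp <- -Inf
    for (k in codes) {
      pk <- suit[[as.character(k)]][i]
      if (pk > mtss[[as.character(k)]] && pk > bp) { B <- k; bp <- pk }
    }
    fit <- fits[[as.character(B)]]
    ca <- agbc_oracle(fit, half, climate_now$mat[i], climate_now$map[i])
    cac <- agbc_oracle(fit, half, climate_future$mat[i],
                       climate_future$map[i])
    out$type[i] <- B
    out$age[i] <- half
    out$c_age[i] <- ca
    out$c_climate[i] <- cac - ca
    out$c_co2[i] <- (F - 1) * ca
    out$status[i] <- 4L
    tot <- tot + areas[i]
  }
  out$c_total <- out$c_age + out$c_climate + out$c_co2
  out
}
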