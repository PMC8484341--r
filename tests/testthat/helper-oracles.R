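# Independent oracles, implemented without sharing code with the package.

# --- MODWT via explicit equivalent filters --------------------------------
# Level-j equivalent MODWT filters built by the upsample-and-convolve
# cascade, then applied by direct circular convolution. This is a different
# algorithm from the package's pyramid recursion.
oracle_modwt <- function(x, wavelet = "haar", J = 6) {
  filt <- switch(wavelet,
    haar = list(g = c(1, 1) / sqrt(2), h = c(1, -1) / sqrt(2)),
    d4 = {
      g <- c(0.4829629131445341, 0.8365163037378079,
             0.2241438680420134, -0.1294095225512604)
      list(g = g, h = rev(g) * c(1, -1, 1, -1))
    })
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  upsample <- function(f, k) {
    out <- numeric((length(f) - 1) * k + 1)
    out[seq(1, length(out), by = k)] <- f
    out
  }
  conv_full <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      idx <- i:(i + length(b) - 1)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  n <- length(x)
  circ_filter <- function(f) {
    vapply(seq_len(n), function(t) {
      l <- seq_along(f) - 1
      sum(f * x[((t - 1 - l) %% n) + 1])
    }, numeric(1))
  }
  W <- vector("list", J)
  g_casc <- 1       # cascade of scaling filters up to level j-1
  for (j in seq_len(J)) {
    h_j <- conv_full(g_casc, upsample(ht, 2^(j - 1)))
    W[[j]] <- circ_filter(h_j)
    g_casc <- conv_full(g_casc, upsample(gt, 2^(j - 1)))
  }
  V <- circ_filter(g_casc)
  list(W = W, V = V)
}

# --- FCS 3.0 byte-level parser --------------------------------------------
# Bare-bones parser written against the standard text, not against the
# package reader: header offsets -> TEXT keyword pairs -> float32 matrix.
oracle_read_fcs <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(bytes[1:6]) == "FCS3.0")
  getoff <- function(k) {
    s <- rawToChar(bytes[(11 + (k - 1) * 8):(10 + k * 8)])
    as.integer(trimws(s))
  }
  txt <- rawToChar(bytes[(getoff(1) + 1):(getoff(2) + 1)])
  delim <- substr(txt, 1, 1)
  fields <- strsplit(substr(txt, 2, nchar(txt)), delim, fixed = TRUE)[[1]]
  keys <- fields[c(TRUE, FALSE)]
  vals <- fields[c(FALSE, TRUE)]
  kv <- function(k) vals[match(k, keys)]
  npar <- as.integer(kv("$PAR"))
  ntot <- as.integer(kv("$TOT"))
  stopifnot(kv("$DATATYPE") == "F", kv("$MODE") == "L")
  dbeg <- as.integer(kv("$BEGINDATA"))
  vals_num <- readBin(bytes[(dbeg + 1):length(bytes)], "numeric",
                      n = npar * ntot, size = 4,
                      endian = if (substr(kv("$BYTEORD"), 1, 1) == "1")
                        "little" else "big")
  m <- matrix(vals_num, nrow = ntot, byrow = TRUE)
  colnames(m) <- vapply(seq_len(npar),
                        function(j) kv(sprintf("$P%dN", j)), "")
  m
}

# --- brute-force pulse H/A/W ----------------------------------------------
# Sample-scan on a 100x oversampled linear interpolation of the pulse.
oracle_haw <- function(pulse, baseline, dt = 0.1, width_fraction = 0.5) {
  height <- max(pulse) - baseline
  if (height <= 0) return(list(height = 0, area = 0, width = 0))
  area <- sum(pmax(pulse - baseline, 0)) * dt
  tfine <- seq(0, (length(pulse) - 1) * dt, by = dt / 100)
  yfine <- approx(seq(0, by = dt, length.out = length(pulse)), pulse,
                  tfine)$y
  lvl <- baseline + width_fraction * height
  above <- which(yfine >= lvl)
  width <- (tfine[max(above)] - tfine[min(above)])
  list(height = height, area = area, width = width)
}

# adjusted Rand index for partition agreement
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  sij <- ch2(tab)
  sa <- ch2(rowSums(tab)); sb <- ch2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_idx <- sa * sb / n2
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}
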