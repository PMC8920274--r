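# Shared fixtures, built in code at test time.

# Random valid primary sequence over the 20-AA alphabet.
randomPrimary <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aminoAcids(), len, replace = TRUE), collapse = "")
}

# Random secondary string over {L,E,H}.
randomSecondary <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("L", "E", "H"), len, replace = TRUE), collapse = "")
}

# Brute-force successor-table checker used as the oracle for the
# grammar-kernel convolution (independent of the kernel machinery).
SUCCESSOR_TABLE <- list(L = c("L", "E", "H", "O"), E = c("L", "E"),
                        H = c("L", "H"), X = c("X", "J"), J = "L",
                        O = "X")

bruteForceViolations <- function(secondary) {
  ch <- strsplit(secondary, "")[[1]]
  vapply(seq_len(length(ch) - 1L), function(i) {
    as.numeric(!(ch[i + 1L] %in% SUCCESSOR_TABLE[[ch[i]]]))
  }, numeric(1))
}

# Tiny deterministic scramble corpus for USM tests: per-sequence K/R
# content is varied so composition carries a strong, recoverable signal.
usmToyData <- function(n, seed, a = 3, b = 5, noiseSd = 0.1,
                       lenRange = c(25, 65)) {
  set.seed(seed)
  seqs <- character(n)
  frac <- numeric(n)
  other <- setdiff(aminoAcids(), c("K", "R"))
  for (i in seq_len(n)) {
    len <- sample(lenRange[1]:lenRange[2], 1)
    q <- runif(1, 0, 0.4)
    ch <- ifelse(runif(len) < q, sample(c("K", "R"), len, replace = TRUE),
                 sample(other, len, replace = TRUE))
    seqs[i] <- paste(ch, collapse = "")
    frac[i] <- mean(ch %in% c("K", "R"))
  }
  ec50 <- a - b * frac + rnorm(n, 0, noiseSd)
  data.frame(sequence = seqs, frac = frac, ec50 = ec50,
             stringsAsFactors = FALSE)
}
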