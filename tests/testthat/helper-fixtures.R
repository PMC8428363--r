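# Shared fixtures, built once per test run and memoized: slide rendering and
# backend training are the expensive steps, so every file draws from this
# cache instead of regenerating.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, builder(), envir = .fx)
  }
  get(key, envir = .fx)
}

# one 800x800 single-tile slide; tumor region covers the whole tile when
# tumor = TRUE, otherwise only non-tumor cells are planted
fxTilePair <- function(seed, tumor = TRUE, posfrac = 0.7,
                       density = 150, fm = "none") {
  key <- paste("tile", seed, tumor, posfrac, density, fm, sep = "_")
  fxMemo(key, function() {
    sp <- slideSpec(
      widthPx = 800, heightPx = 800,
      nTumorRegions = as.integer(tumor), tumorRegionCover = "full",
      positiveFraction = posfrac, tumorCellDensity = density,
      nontumorCellDensity = 60, failureMode = fm, seed = seed
    )
    s <- generateSlide(sp, slideId = sprintf("fx%s_%d", tumor, seed))
    tile <- partitionTiles(s$slide)[[1]]
    tile@label <- if (tumor) "tumor" else "non-tumor"
    list(tile = tile, truth = s$truth)
  })
}

# 800x800 slides with a partial tumor region: contain all four cell classes
fxMixedPair <- function(seed, posfrac = 0.7, density = 200) {
  key <- paste("mixed", seed, posfrac, density, sep = "_")
  fxMemo(key, function() {
    sp <- slideSpec(
      widthPx = 800, heightPx = 800, nTumorRegions = 1,
      positiveFraction = posfrac, tumorCellDensity = density,
      nontumorCellDensity = 60, seed = seed
    )
    s <- generateSlide(sp, slideId = sprintf("mix%d", seed))
    tile <- partitionTiles(s$slide)[[1]]
    tile@label <- "tumor"
    list(tile = tile, truth = s$truth)
  })
}

fxTileClassifier <- function() {
  fxMemo("tileClassifier", function() {
    tiles <- c(
      lapply(1:6, function(s) fxTilePair(s, tumor = TRUE, density = 120)$tile),
      lapply(11:16, function(s) fxTilePair(s, tumor = FALSE)$tile)
    )
    trainTileClassifier(tiles, seed = 3)
  })
}

fxCellModel <- function() {
  fxMemo("cellModel", function() {
    pairs <- lapply(1:5, fxMixedPair)
    trainCellModel(
      lapply(pairs, `[[`, "tile"),
      lapply(pairs, function(x) tileCellTable(x$truth, x$tile)),
      seed = 4
    )
  })
}

# brute-force oracles -------------------------------------------------------

# Harrell's c by exhaustive pairwise enumeration (ties in score = 0.5)
bruteCindex <- function(time, event, risk) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # comparable: the smaller time is an event
      ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
      if (ti == tj && ei && ej) next # tied event times: not usable
      if (ti < tj && !ei) next
      if (tj < ti && !ej) next
      if (ti == tj && !(ei && ej)) {
        # one event, one censored at same time: event is "first"
        if (!ei && !ej) next
      }
      shorter <- if (ti < tj || (ti == tj && ei && !ej)) i else j
      longer <- if (shorter == i) j else i
      den <- den + 1
      if (risk[shorter] > risk[longer]) num <- num + 1
      else if (risk[shorter] == risk[longer]) num <- num + 0.5
    }
  }
  num / den
}

# log-rank chi-square by direct observed-minus-expected accumulation
bruteLogrank <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == levels(group)[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == levels(group)[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small deterministic survival datasets
fxSurvData <- function(n, seed, censorRate = 0.3) {
  set.seed(seed)
  risk <- rnorm(n)
  time <- rexp(n, rate = exp(0.8 * risk) * 0.2)
  cens <- rexp(n, rate = censorRate * 0.2)
  list(time = pmin(time, cens), event = time <= cens, risk = risk)
}
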