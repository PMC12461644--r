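## Shared (memoized) fixtures: tokenizer, tiny models, and the two
## desk-scale training studies used by the acceptance tests. Each study
## trains once per session and is reused by every test that needs it.

.modelCache <- new.env(parent = emptyenv())

cachedTokenizer <- function() {
  if (is.null(.modelCache$tok)) {
    .modelCache$tok <- bpeTrain(templateLexicon(), 400L)
  }
  .modelCache$tok
}

## 4-domain, 2-dataset corpus for the contrastive pre-training study
dualEncoderLayout <- function() {
  list(
    list(name = "dsA", domains = list(
      makeDomainSpec("A-T1", "T1-weighted"),
      makeDomainSpec("A-T2", "T2-weighted"))),
    list(name = "dsB", domains = list(
      makeDomainSpec("B-T1s", "T1-weighted", skullStrip = TRUE),
      makeDomainSpec("B-T2s", "T2-weighted", skullStrip = TRUE))))
}

canonicalDomainPrompts <- function(corpus) {
  doms <- unique(vapply(corpus, function(r) r$domain, character(1)))
  out <- list()
  for (d in doms) {
    out[[d]] <- Filter(function(r) r$domain == d, corpus)[[1L]]$prompt
  }
  out
}

## contrastive pre-training study: ~400 slices, 64x64, fixed seed
cachedDualEncoderStudy <- function() {
  if (is.null(.modelCache$dualEnc)) {
    set.seed(42)
    corpus <- buildSliceCorpus(dualEncoderLayout(), nSubjects = 100L,
                               seed = 5L, size = 64L)
    tok <- cachedTokenizer()
    tm <- buildTextEncoder(tinyTextEncoderConfig(), tok)
    im <- buildImageEncoder(tinyImageEncoderConfig())
    train <- Filter(function(r) r$split == "train", corpus)
    val <- lapply(Filter(function(r) r$split == "val", corpus),
                  function(r) list(image = r$image, domain = r$domain))
    res <- pretrainDualEncoder(train, tm, im, epochs = 10L, batchSize = 20L,
                               lr = 1e-3, valSet = val,
                               domainPrompts = canonicalDomainPrompts(corpus))
    .modelCache$dualEnc <- list(text = tm, image = im, corpus = corpus,
                              log = res$log)
  }
  .modelCache$dualEnc
}

## translation study: 5 seen domains (dsA T1/T2/T1fs, dsB T1s/T2s) plus the
## held-out attribute combination T2fs as the zero-shot target
translationLayout <- function() defaultCorpusLayout()

zeroShotDomainSpec <- function() {
  makeDomainSpec("A-T2fs", "T2-weighted", fatSat = TRUE)
}

cachedTranslationStudy <- function() {
  if (is.null(.modelCache$trans)) {
    set.seed(202)
    pretrainCorpus <- buildSliceCorpus(translationLayout(), nSubjects = 60L,
                                       seed = 7L, size = 64L)
    tok <- cachedTokenizer()
    tm <- buildTextEncoder(tinyTextEncoderConfig(), tok)
    im <- buildImageEncoder(tinyImageEncoderConfig())
    ptrain <- Filter(function(r) r$split == "train", pretrainCorpus)
    pretrainDualEncoder(ptrain, tm, im, epochs = 5L, batchSize = 20L,
                        lr = 1e-3)
    corpus <- buildSliceCorpus(translationLayout(), nSubjects = 10L,
                               seed = 8L, size = 64L)
    cfg <- experimentConfig(initEpochs = 10L, fineEpochs = 3L, batchSize = 6L,
                            lr = 1e-3, imageSize = 64L, rank = 8L,
                            hidden = 48L, maxStepsPerEpoch = 20L)
    fit <- trainTwoStage(corpus, tm, im, config = cfg)
    best <- selectBestModel(fit$history)
    applyCheckpoint(fit, best)
    .modelCache$trans <- list(text = tm, image = im, corpus = corpus,
                              fit = fit, best = best)
  }
  .modelCache$trans
}

## PSNR of translated-vs-target and the identity (input-vs-target) baseline
## for every seen ordered domain pair available in the test split
seenPairGains <- function(study) {
  corpus <- study$corpus
  fit <- study$fit
  test <- Filter(function(r) r$split == "test", corpus)
  keys <- vapply(test, function(r) r$pairingKey, character(1))
  gains <- list()
  for (k in unique(keys)) {
    recs <- test[keys == k]
    if (length(recs) < 2L) next
    for (a in seq_along(recs)) for (b in seq_along(recs)) {
      if (a == b) next
      rs <- recs[[a]]; rt <- recs[[b]]
      out <- decodeConditional(fit$decoder,
                               encodeStructure(fit$struct, rs$image),
                               fit$domainEncodings[[rt$domain]])
      key <- paste(rs$domain, rt$domain, sep = "->")
      gains[[key]] <- c(gains[[key]],
                        psnr(out, rt$image) - psnr(rs$image, rt$image))
    }
  }
  vapply(gains, mean, numeric(1))
}

## zero-shot gain: translate test T1 slices of dsA into the held-out T2fs
## domain (prompt only; never trained) and compare against identity
zeroShotGain <- function(study) {
  corpus <- study$corpus
  fit <- study$fit
  zdom <- zeroShotDomainSpec()
  tz <- encodeText(study$text, domainPrompt(zdom))
  test <- Filter(function(r) r$split == "test" && r$domain == "A-T1", corpus)
  gains <- vapply(test, function(rs) {
    target <- renderDomain(generateStructure(rs$structureSeed, size = 64L), zdom)
    out <- decodeConditional(fit$decoder,
                             encodeStructure(fit$struct, rs$image), tz)
    psnr(out, target) - psnr(rs$image, target)
  }, numeric(1))
  mean(gains)
}
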