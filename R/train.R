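## Two-stage training orchestration: inner-subject supervision first
## (reconstruction + structure consistency on paired slices), then
## cross-dataset collaborative learning (triangular consistency,
## least-squares adversarial and cosine semantic terms with unpaired
## intermediates from other datasets of the same organ).

#' Experiment configuration
#'
#' Full-scale defaults follow the published schedule: 5 initial epochs and
#' 45 fine-tuning epochs at batch size 6 with AdamW at learning rate 1e-4
#' on 256x256 slices; the contrastive pre-training uses batch 60 for 50
#' epochs.
#'
#' @param initEpochs,fineEpochs stage schedules (`fineEpochs = 0` trains
#'   stage 1 only)
#' @param batchSize slices per step (pairs per step = `batchSize / 2`)
#' @param lr AdamW learning rate
#' @param imageSize slice size
#' @param weights a [lossWeights()]
#' @param rank,hidden hyper-network size of decoder and discriminator
#' @param pretrainEpochs,pretrainBatch contrastive pre-training schedule
#' @param maxValPairs validation pairs scored per epoch
#' @param maxStepsPerEpoch optimisation steps per epoch; `Inf` means one
#'   pass over the paired training groups (groups are resampled when more
#'   steps are requested than one pass provides)
#' @param lrDecay per-epoch multiplicative learning-rate decay (1 = none)
#' @export
experimentConfig <- function(initEpochs = 5L, fineEpochs = 45L, batchSize = 6L,
                             lr = 1e-4, imageSize = 256L,
                             weights = lossWeights(), rank = 4L, hidden = 32L,
                             pretrainEpochs = 50L, pretrainBatch = 60L,
                             maxValPairs = 6L, maxStepsPerEpoch = Inf,
                             lrDecay = 1) {
  stopifnot(initEpochs >= 1L, fineEpochs >= 0L, batchSize >= 2L, lr > 0)
  structure(list(initEpochs = as.integer(initEpochs),
                 fineEpochs = as.integer(fineEpochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 imageSize = as.integer(imageSize), weights = weights,
                 rank = as.integer(rank), hidden = as.integer(hidden),
                 pretrainEpochs = as.integer(pretrainEpochs),
                 pretrainBatch = as.integer(pretrainBatch),
                 maxValPairs = as.integer(maxValPairs),
                 maxStepsPerEpoch = maxStepsPerEpoch,
                 lrDecay = lrDecay),
            class = "experimentConfig")
}

corpusGroups <- function(corpus, split) {
  idx <- which(vapply(corpus, function(r) r$split == split, logical(1)))
  keys <- vapply(idx, function(i) corpus[[i]]$pairingKey, character(1))
  gr <- split(idx, keys)
  gr[vapply(gr, length, integer(1)) >= 2L]
}

domainEncodings <- function(corpus, textModel) {
  doms <- unique(vapply(corpus, function(r) r$domain, character(1)))
  out <- list()
  for (d in doms) {
    r <- corpus[[which(vapply(corpus, function(r) r$domain == d, logical(1)))[1L]]]
    out[[d]] <- encodeText(textModel, r$prompt)
  }
  out
}

imgNode <- function(img) agNode(array(img, dim = c(dim(img), 1L, 1L)))

rowNode <- function(v) agNode(matrix(v, nrow = 1L))

## generator-side loss node for one paired sample (+ optional intermediate)
pairLossNode <- function(structModel, decoder, rs, rt, tEnc, w, extractor,
                         stage, interRec = NULL, disc = NULL, imageModel = NULL) {
  xs <- imgNode(rs$image); xt <- imgNode(rt$image)
  tS <- rowNode(tEnc[[rs$domain]]); tT <- rowNode(tEnc[[rt$domain]])
  phiS <- fwStructureEncoder(structModel, xs)
  phiT <- fwStructureEncoder(structModel, xt)
  xtP <- fwConditionalDecoder(decoder, phiS, tT)
  xsP <- fwConditionalDecoder(decoder, phiT, tS)
  comps <- list(
    rec = reconstructionLoss(xs, xt, xsP, xtP, extractor, w),
    con = structureConsistencyLoss(phiS, phiT,
                                   (rs$image > 0) & (rt$image > 0), w$tau))
  if (stage == "fine") {
    tI <- rowNode(tEnc[[interRec$domain]])
    xiP <- fwConditionalDecoder(decoder, phiS, tI)
    phiI <- fwStructureEncoder(structModel, xiP)
    xi2t <- fwConditionalDecoder(decoder, phiI, tT)
    comps$tri <- triangularLoss(xi2t, xt, extractor, w)
    sFake <- fwDiscriminator(disc, xiP, tI)
    ones <- sFake$val; ones[] <- 1
    comps$adv <- agMeanSqDiff(sFake, agNode(ones))
    comps$cos <- cosineSemanticLoss(fwImageEncoder(imageModel, xiP), tI)
    comps$xiP <- NULL
    attr(comps, "fake") <- xiP$val
  }
  comps
}

#' Train the translation triad with the two-stage schedule
#'
#' Stage "init" minimises reconstruction + structure-consistency losses on
#' paired slices; stage "fine" adds the triangular, adversarial and cosine
#' terms with intermediate slices drawn from other datasets of the same
#' organ inside the mini-batch. The text encoder is frozen throughout; the
#' image encoder (frozen) scores the cosine semantic loss. Per-step loss
#' components are logged, model snapshots and validation PSNR per epoch.
#'
#' @param corpus slice corpus from [buildSliceCorpus()] (records with
#'   image, prompt, dataset, domain, organ, pairingKey, split)
#' @param textModel frozen text encoder
#' @param imageModel frozen image encoder (required when `fineEpochs > 0`)
#' @param config an [experimentConfig()]
#' @param structCfg,discCfg architecture configurations
#' @param extractor perceptual feature extractor
#' @param verbose print per-epoch summaries
#' @return list with the trained `struct`/`decoder`/`disc` models, the
#'   per-step `stepLog`, the per-epoch `history` (with parameter
#'   snapshots) and the domain encodings used
#' @export
trainTwoStage <- function(corpus, textModel, imageModel = NULL,
                          config = experimentConfig(),
                          structCfg = tinyStructureEncoderConfig(),
                          discCfg = tinyDiscriminatorConfig(),
                          extractor = mkFeatureExtractor(),
                          verbose = FALSE) {
  w <- config$weights
  dcond <- textModel$cfg$projectionDim
  structModel <- buildStructureEncoder(structCfg)
  decoder <- buildConditionalDecoder(structCfg, dcond, rank = config$rank,
                                     hidden = config$hidden)
  disc <- buildDiscriminator(discCfg, dcond, rank = config$rank,
                             hidden = config$hidden)
  tEnc <- domainEncodings(corpus, textModel)
  trainGroups <- corpusGroups(corpus, "train")
  valGroups <- corpusGroups(corpus, "val")
  if (length(trainGroups) == 0L) stop("no paired training subjects (missing pairing keys?)")
  trainIdx <- which(vapply(corpus, function(r) r$split == "train", logical(1)))
  paramsG <- c(agParams(structModel[c("stem", "stages")]),
               agParams(decoder[c("stage2", "up2", "stage1", "up1", "head")]))
  optG <- agAdamW(paramsG, lr = config$lr)
  paramsD <- agParams(disc[c("stem", "blocks", "attns", "head")])
  optD <- agAdamW(paramsD, lr = config$lr)
  pairsPerStep <- max(1L, config$batchSize %/% 2L)
  stepsPerEpoch <- if (is.finite(config$maxStepsPerEpoch)) {
    as.integer(config$maxStepsPerEpoch)
  } else {
    max(1L, length(trainGroups) %/% pairsPerStep)
  }
  stepLog <- list()
  history <- list()

  sampleInter <- function(rs) {
    cand <- trainIdx[vapply(trainIdx, function(i) {
      corpus[[i]]$dataset != rs$dataset && corpus[[i]]$organ == rs$organ
    }, logical(1))]
    if (length(cand) == 0L) {
      stop("fine stage needs a second dataset with the same organ")
    }
    corpus[[cand[sample.int(length(cand), 1L)]]]
  }

  epochCounter <- 0L
  runStage <- function(stage, epochs) {
    for (ep in seq_len(epochs)) {
      lrNow <- config$lr * config$lrDecay^epochCounter
      optG$lr <- lrNow
      optD$lr <- lrNow
      epochCounter <<- epochCounter + 1L
      for (st in seq_len(stepsPerEpoch)) {
        gs <- sample.int(length(trainGroups), pairsPerStep,
                         replace = pairsPerStep > length(trainGroups))
        pairComps <- lapply(gs, function(g) {
          ids <- trainGroups[[g]]
          two <- sample(ids, 2L)
          rs <- corpus[[two[1L]]]; rt <- corpus[[two[2L]]]
          inter <- if (stage == "fine") sampleInter(rs) else NULL
          list(comps = pairLossNode(structModel, decoder, rs, rt, tEnc, w,
                                    extractor, stage, inter, disc, imageModel),
               inter = inter)
        })
        np <- length(pairComps)
        nm <- if (stage == "init") c("rec", "con") else
          c("rec", "con", "tri", "adv", "cos")
        avg <- lapply(nm, function(cn) {
          agLinComb(lapply(pairComps, function(p) p$comps[[cn]]), rep(1 / np, np))
        })
        names(avg) <- nm
        rep_ <- totalLoss(avg, stage, w)
        agZeroGrad(paramsG)
        agBackward(rep_$total)
        agStep(optG)
        if (stage == "fine") {
          dnodes <- lapply(pairComps, function(p) {
            tI <- rowNode(tEnc[[p$inter$domain]])
            sReal <- fwDiscriminator(disc, imgNode(p$inter$image), tI)
            sFake <- fwDiscriminator(disc, agNode(array(attr(p$comps, "fake"),
                                                        dim = dim(attr(p$comps, "fake")))), tI)
            ones <- sReal$val; ones[] <- 1
            agLinComb(list(agMeanSqDiff(sReal, agNode(ones)),
                           agMeanSqDiff(sFake, agNode(ones * 0))), c(1, 1))
          })
          dLoss <- agLinComb(dnodes, rep(1 / np, np))
          agZeroGrad(paramsD)
          agBackward(dLoss)
          agStep(optD)
        }
        row <- c(lapply(avg, function(n) as.numeric(n$val)),
                 list(total = as.numeric(rep_$total$val),
                      dloss = if (stage == "fine") as.numeric(dLoss$val) else NA_real_,
                      stage = stage, epoch = ep, step = st))
        stepLog[[length(stepLog) + 1L]] <<- row
      }
      valPSNR <- validatePSNR(corpus, valGroups, structModel, decoder, tEnc,
                              config$maxValPairs)
      history[[length(history) + 1L]] <<- list(
        stage = stage, epoch = ep, valPSNR = valPSNR,
        params = list(struct = snapshotParams(stripStatic(structModel)),
                      decoder = snapshotParams(stripStatic(decoder))))
      if (verbose) {
        message(sprintf("[%s %d/%d] total=%.4f valPSNR=%.2f", stage, ep,
                        epochs, as.numeric(rep_$total$val), valPSNR))
      }
    }
  }

  runStage("init", config$initEpochs)
  if (config$fineEpochs > 0L) {
    if (is.null(imageModel)) stop("fine stage requires the frozen image encoder")
    runStage("fine", config$fineEpochs)
  }
  list(struct = structModel, decoder = decoder, disc = disc,
       stepLog = stepLogFrame(stepLog), history = history,
       domainEncodings = tEnc, config = config)
}

stepLogFrame <- function(stepLog) {
  if (length(stepLog) == 0L) return(data.frame())
  cols <- unique(unlist(lapply(stepLog, names)))
  do.call(rbind, lapply(stepLog, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    as.data.frame(r[cols])
  }))
}

validatePSNR <- function(corpus, valGroups, structModel, decoder, tEnc,
                         maxPairs) {
  if (length(valGroups) == 0L) return(NA_real_)
  gs <- valGroups[seq_len(min(maxPairs, length(valGroups)))]
  ps <- vapply(gs, function(ids) {
    rs <- corpus[[ids[1L]]]; rt <- corpus[[ids[2L]]]
    out <- decodeConditional(decoder,
                             encodeStructure(structModel, rs$image),
                             tEnc[[rt$domain]])
    psnr(out, rt$image)
  }, numeric(1))
  mean(ps)
}

#' Select the checkpoint with the best validation PSNR
#'
#' @param history the `history` element of [trainTwoStage()]'s result
#' @return the winning history entry (parameters snapshot, stage, epoch);
#'   ties resolve to the latest epoch
#' @export
selectBestModel <- function(history) {
  if (length(history) == 0L) stop("empty checkpoint history")
  ps <- vapply(history, function(h) h$valPSNR, numeric(1))
  if (all(is.na(ps))) return(history[[length(history)]])
  best <- max(ps, na.rm = TRUE)
  history[[max(which(ps == best))]]
}

#' Restore a history entry's parameters into built models
#' @param models list with `struct` and `decoder` models
#' @param entry a history entry from [selectBestModel()]
#' @export
applyCheckpoint <- function(models, entry) {
  restoreParams(stripStatic(models$struct), entry$params$struct)
  restoreParams(stripStatic(models$decoder), entry$params$decoder)
  invisible(models)
}
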