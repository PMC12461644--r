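test_that("the prompt template renders the canonical domain sentence", {
  kw <- extractKeywords(overrides = list(
    Organ = "brain", Modality = "magnetic resonance imaging",
    Sequence = "T2-weighted", Plane = "axial"))
  p <- renderPrompt(kw)
  expect_identical(
    promptSentences(p)[1],
    "A T2-weighted magnetic resonance imaging of the brain for the subject.")
  expect_identical(promptSentences(p)[length(p)],
                   "The image is visualized in the axial plane.")
  ## no contrast keyword -> no contrast sentence
  expect_false(any(grepl("contrast-enhanced scan", promptSentences(p))))
})

test_that("keyword extraction normalises tags and respects overrides", {
  kw <- extractKeywords(
    tags = list(Manufacturer = "Philips", MagneticFieldStrength = 3.0,
                Organ = "head"),
    overrides = list(Organ = "brain", Modality = "MR", Plane = "Axial"))
  expect_identical(keywordToken(kw, "Manufacturer"), "Philips")
  expect_identical(keywordToken(kw, "MagneticFieldStrength"), "3.0")
  expect_identical(keywordToken(kw, "Organ"), "brain")       # override wins
  expect_identical(keywordToken(kw, "Modality"), "magnetic resonance imaging")
  expect_identical(keywordToken(kw, "Plane"), "axial")
  expect_true(is.na(keywordToken(kw, "EchoTime")))           # absent in, absent out
  ## unknown tags are ignored
  kw2 <- extractKeywords(tags = list(PatientName = "X", FlipAngle = 90),
                         overrides = list(Organ = "brain", Modality = "MR",
                                          Plane = "axial"))
  expect_identical(keywordToken(kw2, "FlipAngle"), "90")
  ## missing essentials are a hard error
  expect_error(extractKeywords(tags = list(Manufacturer = "Philips")),
               "essential")
})

test_that("scanner and acquisition sentences adapt to available keywords", {
  kw <- extractKeywords(
    tags = list(MagneticFieldStrength = 1.5, EchoTime = 4.6, FlipAngle = 9),
    overrides = list(Organ = "breast", Modality = "MR", Plane = "coronal",
                     Sequence = "T1-weighted"))
  s <- promptSentences(renderPrompt(kw))
  expect_true("The scan is acquired on the 1.5 Tesla scanner." %in% s)
  expect_true(paste("The image is acquired using a 9 degree flip angle,",
                    "an echo time of 4.6 ms.") %in% s)
})

test_that("time points render as ordinals inside the domain sentence", {
  kw <- extractKeywords(overrides = list(
    Organ = "breast", Modality = "MR", Plane = "axial",
    Sequence = "dynamic contrast-enhanced", SequenceFrameNumber = 2))
  expect_identical(
    promptSentences(renderPrompt(kw))[1],
    "A second dynamic contrast-enhanced magnetic resonance imaging of the breast for the subject.")
})

test_that("essential flags follow the appearance-defining tokens", {
  kw <- extractKeywords(
    tags = list(Manufacturer = "Philips", EchoTime = 10),
    overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
                     Sequence = "T1-weighted", Contrast = "Gadolinium",
                     Preprocess = "skull removal"))
  p <- renderPrompt(kw)
  s <- promptSentences(p); e <- promptEssential(p)
  expect_true(e[grepl("^A T1-weighted", s)])
  expect_true(e[grepl("contrast-enhanced scan", s)])
  expect_true(e[grepl("preprocessing", s)])
  expect_false(e[grepl("scanner", s)])
  expect_false(e[grepl("acquired using", s)])
  expect_false(e[grepl("visualized", s)])
})

test_that("prompt rendering is injective over differing essential tokens", {
  set.seed(20)
  for (i in 1:25) {
    k1 <- randomKeywordSet(); k2 <- randomKeywordSet()
    p1 <- promptText(renderPrompt(k1)); p2 <- promptText(renderPrompt(k2))
    ess <- c("Organ", "Modality", "Sequence", "Contrast", "Preprocess")
    differ <- any(vapply(ess, function(nm) {
      !identical(keywordToken(k1, nm), keywordToken(k2, nm))
    }, logical(1)))
    if (differ) expect_false(identical(p1, p2))
  }
})

test_that("augmentation keeps essential sentences and is seed-deterministic", {
  kw <- extractKeywords(
    tags = list(Manufacturer = "Philips", MagneticFieldStrength = 3,
                EchoTime = 5, RepetitionTime = 9),
    overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
                     Sequence = "T1-weighted", Contrast = "Gadolinium"))
  p <- renderPrompt(kw)
  set.seed(1); a1 <- augmentPrompt(p, 0.5)
  set.seed(1); a2 <- augmentPrompt(p, 0.5)
  expect_identical(promptSentences(a1), promptSentences(a2))
  ## drop everything optional
  set.seed(2); a3 <- augmentPrompt(p, 1)
  expect_setequal(promptSentences(a3), promptSentences(p, essentialOnly = TRUE))
  ## a prompt with only essential sentences is untouched as a multiset
  pe <- renderPrompt(extractKeywords(overrides = list(
    Organ = "brain", Modality = "MR", Plane = "axial")))
  onlyEss <- new("MedicalPrompt",
                 sentences = promptSentences(pe)[promptEssential(pe)],
                 essential = rep(TRUE, sum(promptEssential(pe))),
                 subjectKey = "", domainKey = "")
  set.seed(3); a4 <- augmentPrompt(onlyEss, 0.9)
  expect_setequal(promptSentences(a4), promptSentences(onlyEss))
})

test_that("the matching rule is reflexive, tolerant of drops, and asymmetric", {
  kw <- extractKeywords(
    tags = list(Manufacturer = "Philips", EchoTime = 5),
    overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
                     Sequence = "T1-weighted"))
  p <- renderPrompt(kw)
  expect_true(matchPrompts(p, p))
  ## candidate = original minus one optional sentence
  keep <- promptEssential(p) | !grepl("scanner", promptSentences(p))
  pm <- new("MedicalPrompt", sentences = promptSentences(p)[keep],
            essential = promptEssential(p)[keep], subjectKey = "", domainKey = "")
  expect_true(matchPrompts(p, pm))
  ## asymmetry: the reduced prompt does not accept the full one as candidate
  ## when the dropped sentence is reinstated (extra sentence in candidate)
  expect_false(matchPrompts(pm, p))
  ## candidate with a foreign sentence never matches
  alien <- new("MedicalPrompt",
               sentences = c(promptSentences(p), "An ultrasound of the knee."),
               essential = c(promptEssential(p), FALSE),
               subjectKey = "", domainKey = "")
  expect_false(matchPrompts(p, alien))
  ## augmented prompts always match their original
  set.seed(11)
  for (i in 1:50) expect_true(matchPrompts(p, augmentPrompt(p, 0.6)))
})

test_that("the match matrix equals exhaustive pairwise rule application", {
  set.seed(33)
  prompts <- lapply(1:8, function(i) renderPrompt(randomKeywordSet()))
  aug <- lapply(prompts, augmentPrompt, dropProb = 0.5)
  M <- buildMatchMatrix(imagePrompts = prompts, textPrompts = aug)
  ## independent re-application of the quoted subset rule
  for (i in seq_along(aug)) {
    for (j in seq_along(prompts)) {
      so <- promptSentences(prompts[[j]])
      sc <- promptSentences(aug[[i]])
      expected <- all(sc %in% so) &&
        all(so[promptEssential(prompts[[j]])] %in% sc)
      expect_identical(M[i, j], as.integer(expected))
    }
  }
  ## one augmented prompt describing two same-protocol subjects: two 1s
  same <- renderPrompt(extractKeywords(overrides = list(
    Organ = "brain", Modality = "MR", Plane = "axial", Sequence = "T1-weighted")))
  M2 <- buildMatchMatrix(imagePrompts = list(same, same), textPrompts = list(same))
  expect_identical(M2, matrix(1L, 1, 2))
})

test_that("prompt text serialisation round-trips with essential flags", {
  p <- renderPrompt(extractKeywords(
    tags = list(Manufacturer = "Philips"),
    overrides = list(Organ = "brain", Modality = "MR", Plane = "axial",
                     Sequence = "T2-weighted")))
  f <- tempfile(fileext = ".txt")
  writePromptText(p, f)
  q <- readPromptText(f)
  expect_identical(promptSentences(q), promptSentences(p))
  expect_identical(promptEssential(q), promptEssential(p))
  unlink(f)
})
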