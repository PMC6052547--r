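# shared fixture builders (everything generated in code)

# strip class/attributes down to a plain numeric matrix for exact comparisons
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

random_profile <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::runif(n * 20), n, 20)
  profile_matrix(x / rowSums(x), source = "teacher")
}

# Write an HHM-format fixture encoding the given probability rows
# (M x 20, columns in aa_alphabet() order). score = round(-1000*log2(p)).
write_hhm_fixture <- function(probs, path, name = "fixture") {
  aa <- aa_alphabet()
  lines <- c(
    "HHsearch 1.5",
    paste("NAME ", name),
    "SEQ",
    paste0("HMM    ", paste(aa, collapse = "\t")),
    "       M->M\tM->I\tM->D\tI->M\tI->I\tD->M\tD->D\tNeff\tNeff_I\tNeff_D",
    "NULL   3706\t5728\t4211\t4064\t4839\t3729\t4763\t4308\t4069\t3323\t5509\t4640\t4464\t4937\t4285\t4423\t3815\t3783\t6325\t4665"
  )
  for (i in seq_len(nrow(probs))) {
    sc <- vapply(probs[i, ], function(p) {
      if (p <= 0) "*" else sprintf("%d", round(-1000 * log2(p)))
    }, character(1))
    cons <- aa[which.max(probs[i, ])]
    lines <- c(lines,
               paste0(cons, " ", i, "\t", paste(sc, collapse = "\t"), "\t", i),
               "       0\t*\t*\t*\t*\t*\t*\t1000\t0\t0")
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

# four-domain toy SCOP-style annotation covering all label cases
toy_annotation <- function() {
  tibble::tibble(
    domain = c("d1", "d2", "d3", "d4", "d5", "d6"),
    class = c("a", "a", "a", "b", "a", "a"),
    fold = c("a.1", "a.1", "a.1", "b.1", "a.2", "a.1"),
    superfamily = c("a.1.1", "a.1.1", "a.1.2", "b.1.1", "a.2.1", "a.1.1"),
    family = c("a.1.1.1", "a.1.1.2", "a.1.2.1", "b.1.1.1", "a.2.1.1", "a.1.1.1")
  )
}

# independent rectangle-sum pAUC oracle (x advances on FP only, so the
# step curve's trapezoids are rectangles)
pauc_oracle <- function(labeled, annotation, fp_limit, tp_max) {
  counts <- table(annotation$superfamily)
  ord <- order(labeled$evalue)
  lab <- as.character(labeled$label[ord])
  sf <- as.character(labeled$query_superfamily[ord])
  keep <- lab != "unknown"
  lab <- lab[keep]; sf <- sf[keep]
  x <- 0; y <- 0; area <- 0
  for (i in seq_along(lab)) {
    w <- 1 / as.numeric(counts[sf[i]])
    if (lab[i] == "FP") {
      dx <- min(w, fp_limit - x)
      area <- area + dx * y
      x <- x + w
      if (x >= fp_limit) break
    } else {
      y <- y + w
    }
  }
  # hit list exhausted inside the budget: the step curve extends flat
  if (x < fp_limit) area <- area + (fp_limit - x) * y
  area / (fp_limit * tp_max)
}

# random labeled hit list over a random annotation
random_labeled_hits <- function(n_hits = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_dom <- 12
  annot <- tibble::tibble(
    domain = sprintf("d%02d", 1:n_dom),
    class = sample(c("a", "b"), n_dom, replace = TRUE),
    fold = NA_character_, superfamily = NA_character_,
    family = NA_character_
  )
  annot$fold <- paste0(annot$class, ".", sample(1:2, n_dom, replace = TRUE))
  annot$superfamily <- paste0(annot$fold, ".", sample(1:2, n_dom, replace = TRUE))
  annot$family <- paste0(annot$superfamily, ".1")
  hits <- tibble::tibble(
    query = sample(annot$domain, n_hits, replace = TRUE),
    subject = sample(annot$domain, n_hits, replace = TRUE),
    evalue = signif(stats::rexp(n_hits), 3)
  )
  list(hits = hits, annotation = annot)
}

# independent hand-unrolled reference: plain R, four-gate formulas written out
unrolled_oracle <- function(model, residues) {
  d <- model$dims$d; H <- model$dims$H
  codes <- match(strsplit(residues, "")[[1]], aa_alphabet())
  sig <- function(x) 1 / (1 + exp(-x))
  h <- rep(0, H); cl <- rep(0, H)
  out <- matrix(0, length(codes), 20)
  for (t in seq_along(codes)) {
    u <- model$embed[codes[t], ]
    a <- as.numeric(u %*% model$Wx + h %*% model$Wh) + model$b
    i <- sig(a[1:H]); f <- sig(a[(H + 1):(2 * H)])
    z <- tanh(a[(2 * H + 1):(3 * H)]); o <- sig(a[(3 * H + 1):(4 * H)])
    cl <- f * cl + i * z
    h <- o * tanh(cl)
    s <- as.numeric(h %*% model$Wy) + model$by
    e <- exp(s - max(s))
    out[t, ] <- e / sum(e)
  }
  out
}
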