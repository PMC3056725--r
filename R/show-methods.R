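setMethod("show", "GeneBudget", function(object) {
  cat("GeneBudget: M =", object@M, ", p =", object@p, ", n =", object@n,
      ", f =", format(object@f, digits = 4), "\n")
  cat("  H(f) =", format(object@Hf, digits = 6), "bits; per-classifier",
      "H_b =", format(object@Hb, digits = 4), "bits\n")
  cat("  Qmax =", format(object@Qmax, digits = 6),
      "-> gene cap", object@gMax, "per binary classifier\n")
})

setMethod("show", "ParityCheckGraph", function(object) {
  cat("ParityCheckGraph:", object@n, "message nodes,", object@m,
      "check nodes,", nrow(object@edges), "edges (column degree",
      paste0(object@j, ";"), "seed", paste0(object@seed, ")"), "\n")
})

setMethod("show", "CodeMatrix", function(object) {
  cat(object@kind, "CodeMatrix:", object@M, "classes x", object@n,
      "binary classifiers, minimum distance", minimumDistance(object), "\n")
  rows <- apply(object@codewords, 1L, paste, collapse = "")
  cat(paste0("  class ", seq_len(object@M), ": ", rows, collapse = "\n"), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@family, ", eta = ", object@eta, "): ",
      "n = ", object@n, ", Q = ", format(object@Q, digits = 4),
      " (g = ", object@g, "), C = ", object@C, "\n", sep = "")
  cat("  inner-CV error", format(min(object@surface$error), digits = 4),
      "over", nrow(object@surface), "grid points\n")
})

setMethod("show", "EcocModel", function(object) {
  cat("EcocModel:", object@code@kind, "code,", object@code@M, "classes,",
      object@code@n, "binary SVMs (C =", paste0(object@C, "),"),
      object@decoding, "decoding\n")
  sizes <- vapply(object@columns, function(col) length(col$genes), integer(1))
  cat("  genes per column:", paste(sizes, collapse = " "),
      "(budget", object@gMax, "each);",
      length(unique(unlist(lapply(object@columns, `[[`, "genes")))),
      "genes overall\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport:", length(object@sets), "gene sets,",
      object@pairs, "pairs; mean Salton stability",
      format(object@mean, digits = 4), "\n")
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport [", object@metric, "]: ",
      length(object@F), " vs ", length(object@G), " values (",
      object@direction, ")\n", sep = "")
  cat("  KS D =", format(object@D, digits = 4),
      "(two-sided p =", format(object@pTwo, digits = 4),
      "; F-left p =", format(object@pLess, digits = 4),
      "; F-right p =", format(object@pGreater, digits = 4), ")\n")
  cat("  verdict at alpha =", object@alpha, ":", object@verdict, "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec (", object@model, "): M = ", object@M, ", p = ",
      object@p, ", q = ", object@q, ", seed ", object@seed, "\n", sep = "")
  if (object@model == "gaussian")
    cat("  ", object@markersPerClass, "markers/class, effect",
        object@effectSize, "sigma, noise sd", object@noiseSigma, "\n")
  else cat("  expression probability f =", object@f, "\n")
})
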