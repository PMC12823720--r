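# Independent from-definition confusion-matrix F1 (test oracle).
oracle_f1 <- function(y_true, y_pred, average = "weighted") {
  lev <- union(unique(as.character(y_true)), unique(as.character(y_pred)))
  f1s <- supports <- numeric(0)
  for (cl in lev) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    sup <- sum(y_true == cl)
    if (sup > 0) { f1s <- c(f1s, f1); supports <- c(supports, sup) }
  }
  if (average == "weighted") sum(f1s * supports) / sum(supports)
  else mean(f1s)
}
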