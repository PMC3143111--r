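# The 6-gene toy network used for all hand-traced expectations:
# protein edges s-a, t-a, s-b, a-b, c-d; no regulatory links;
# co-expression weights s:1 t:1 a:5 b:2 c:0 d:3.
toy_net <- function() {
  ppi <- rbind(c("s", "a"), c("t", "a"), c("s", "b"), c("a", "b"),
               c("c", "d"))
  suppressMessages(assemble_wpi(
    ppi, matrix(character(), ncol = 2L),
    weights = c(s = 1, t = 1, a = 5, b = 2, c = 0, d = 3)))
}

make_expr <- function(mat, genes, conds = NULL) {
  if (is.null(conds)) conds <- sprintf("c%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, conds)
  mat
}
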