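# Scaled-down study configuration used by the fitting tests: three human cell
# types spanning type I-biased (Ramos), mixed (monocyte) and type II-biased
# (A549) receptor ratios, all three ligands, 8 doses.
small_human_config <- function(n_doses = 8) {
  h <- build_human_panel()
  h$panels <- h$panels[c(1, 2, 5)]
  h$doses <- 100e-9 / 3^seq(0, 11, length.out = n_doses)
  h
}

true_log10ka_table <- function(config) {
  do.call(rbind, lapply(config$affinities, function(a)
    data.frame(ligand = a$ligand,
               receptor = c("IL4Ra", "gamma_c", "IL13Ra1"),
               true_log10_ka = log10(c(a$Ka_alpha, a$Ka_gamma, a$Ka_13)))))
}

# Recovery errors respecting the two-receptor exchange symmetry of the
# multivalent model: ligands binding only two chains are compared as sorted
# (unordered) log10 Ka pairs; three-chain ligands elementwise.
recovery_errors <- function(fit, config) {
  truth <- true_log10ka_table(config)
  tab <- merge(fit$ka_table[!fit$ka_table$fixed_no_binding, ], truth)
  errs <- c()
  for (lg in unique(tab$ligand)) {
    d <- tab[tab$ligand == lg, ]
    if (nrow(d) == 2) {
      errs <- c(errs, abs(sort(d$log10_ka) - sort(d$true_log10_ka)))
    } else {
      errs <- c(errs, abs(d$log10_ka - d$true_log10_ka))
    }
  }
  errs
}
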