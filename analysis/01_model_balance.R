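#!/usr/bin/env Rscript
# Control parameterization of the five-state gating scheme, its
# detailed-balance closure, and the ML277 modification rule.
# Writes results/model_parameters.csv and prints the balance report.

suppressMessages(library(kqgate))
dir.create("results", showWarnings = FALSE)

ctrl <- qk_params()
ml <- apply_ml277(ctrl)

bal <- loop_balance_report(ctrl)
cat(sprintf("control loop products: forward %.5g, reverse %.5g, ratio %.4f\n",
            bal$forward_product, bal$reverse_product, bal$ratio))
cat(sprintf("voltage variation of the loop ratio: %.3g (shared slopes)\n",
            bal$max_voltage_variation))
cat(sprintf("ML277 rule: k2 %.2f -> %.2f, c3 %.4f -> %.4f ms^-1 (rebalanced)\n",
            ctrl$k2, ml$k2, ctrl$c3, ml$c3))
cat(sprintf("rebalanced loop ratio: %.4f\n", loop_balance_report(ml)$ratio))

fields <- c("a1", "c1", "m", "n", "a2", "c2", "b", "d", "a3", "c3",
            "k1", "k2", "k3", "k4")
tab <- data.frame(parameter = fields,
                  control = unlist(ctrl[fields]),
                  ml277 = unlist(ml[fields]))
write.csv(tab, "results/model_parameters.csv", row.names = FALSE)
write_params(ctrl, "results/params_control.json")
write_params(ml, "results/params_ml277.json")
cat("wrote results/model_parameters.csv and parameter JSON files\n")
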