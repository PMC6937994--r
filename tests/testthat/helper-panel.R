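# Pooled biomarker accuracies used throughout: procalcitonin and
# lactate, with the published (rounded) likelihood ratios attached.
pct_acc <- function()
  test_accuracy("PCT", 0.88, 0.81,
                sens_ci = c(0.80, 0.93), spec_ci = c(0.67, 0.90),
                lr_positive = 4.63, lr_negative = 0.15)

lactate_acc <- function()
  test_accuracy("lactate", 0.727, 0.962,
                sens_ci = c(0.434, 0.902), spec_ci = c(0.906, 0.985),
                lr_positive = 19.0, lr_negative = 0.28)

case_panel <- function() list(pct_acc(), lactate_acc())

case_strata <- function()
  list(list(label = "intermediate", pretest = 0.14),
       list(label = "high", pretest = 0.278))

# direct Bayes ratio form, the independent oracle for the odds-form update
bayes_ratio_posterior <- function(pretest, sens, spec)
  pretest * sens / (pretest * sens + (1 - pretest) * (1 - spec))
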