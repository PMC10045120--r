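# Gene -> model wiring for per-cell parameterization.
#
# rate_scaled: expression ratio to the cohort average multiplies the named
#   rate constant(s). "A+B" entries are additive: (eA+eB)/(mA+mB).
#   AQP3 scales aquaporin-mediated H2O2 membrane permeation by default; add
#   k34 to its list to also scale drug permeation.
# abundance_set: expression is converted to equilibrium protein abundance and
#   the ratio to the cohort-average protein scales the initial concentrations
#   of the named species pool.
rate_scaled:
  NQO1: k29
  SOD1: k32
  POR: k33
  AQP3: [k_aqp_h2o2]
  GSR: k_gsr
  TXNRD1: k_trxr
  G6PD+GLUD1: k_nadph
abundance_set:
  GPX1: GPX
  CAT: CAT
  PRX1+PRX2: PRX
  TXN: TRX
  GLRX: GRX
pools:
  GPX: [GPX]
  CAT: [CAT]
  PRX: [PRX_SH, PRX_SS, PRX_SO2]
  TRX: [TRX_SH, TRX_SS]
  GRX: [GRX]
multiplier_epsilon: 1.0e-3
expression_scale: 1.0
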