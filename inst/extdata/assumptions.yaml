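# Brand consumption assumptions for shipment-to-user conversion.
# central: sticks per user per day; mode: how sensitivity bounds are formed.
brands:
  "KT&G":
    central: 12
    mode: multiplicative_user_bounds
    donor: PMI
    rounding: 0
  BAT:
    central: 7.6
    mode: multiplicative_user_bounds
    donor: BAT
    rounding: 1
  JT:
    central: 7.6
    mode: multiplicative_user_bounds
    donor: BAT
    rounding: 1
# Common literature-based consumption parameter for the shipment-only series.
literature:
  central: 7.3
  ci: [6.33, 8.27]
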