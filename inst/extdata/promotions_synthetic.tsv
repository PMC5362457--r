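# Manual-review promotions: mutations raised to high confidence after
# expert review.
gene	aa_change	justification
SRC	Thr524HisfsTer52	frameshift in the C-terminal regulatory tail replaces the inhibitory Tyr530, most likely activating
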