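name	epsilon_r	volume	template
water	80.10	17.7896	water.xyz
methanol	32.94	36.2745	methanol.xyz
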