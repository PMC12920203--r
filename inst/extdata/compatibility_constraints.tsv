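strain_a	strain_b	outcome
UC4439	UC4449	compatible
UC4439	UC4450	compatible
UC4439	UC4478	compatible
UC4439	UC4490	compatible
UC4439	UC4510	compatible
UC4439	UC4521	antagonistic
UC4439	UC4535	compatible
UC4439	UC4553	compatible
UC4449	UC4450	compatible
UC4449	UC4478	compatible
UC4449	UC4490	compatible
UC4449	UC4510	limited_growth
UC4449	UC4521	compatible
UC4449	UC4535	compatible
UC4449	UC4553	compatible
UC4450	UC4478	compatible
UC4450	UC4490	compatible
UC4450	UC4510	compatible
UC4450	UC4521	antagonistic
UC4450	UC4535	compatible
UC4450	UC4553	compatible
UC4478	UC4490	compatible
UC4478	UC4510	compatible
UC4478	UC4521	antagonistic
UC4478	UC4535	compatible
UC4478	UC4553	compatible
UC4490	UC4510	compatible
UC4490	UC4521	antagonistic
UC4490	UC4535	compatible
UC4490	UC4553	compatible
UC4510	UC4521	compatible
UC4510	UC4535	limited_growth
UC4510	UC4553	limited_growth
UC4521	UC4535	compatible
UC4521	UC4553	compatible
UC4535	UC4553	compatible
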