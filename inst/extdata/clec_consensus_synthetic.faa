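>clec_consensus_synthetic C-terminal CLec-like consensus (synthetic stand-in)
GDFACDKKALPSIAFPNKNTMSKIFEGLEKIYEVLGSMAWIGLNDLQTEDEIAEKVYHSG
MESITAKDGMPVTRDHVNIPFSGLAGTGLEPLRRFRTFYYRFFNNGYYQAHAVDNTPTSC
PEGEANKYHMAGLDSKKDNSAFDVYRPGLKTCYNSGRVRY
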