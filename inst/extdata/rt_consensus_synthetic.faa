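>rt_consensus_synthetic cyanobacterial DGR-RT consensus (synthetic stand-in)
SGWANREQLSNVHGKQKVSRYAYRLFNSQLLEYSVILSWPVAPNASALEIDATKATLPKK
GIPRQLLLKPINGLPKKGRVVYQSVNDDDTYRSANTPGAYVFNLFLEVEKELDCLAGGSS
LRDLNQQIASLEIENPRDLPKMQIATQKGIPQGSEIPPGPWQFGIYRRDDAPYVYKEKTW
DVFWRGSRSAEARGGSDQARLNNRNTSSGYADDRTDEDQTYYPAIASLLMASHGVSVEGL
VHFPGTDPFQLVSVENQIVGILVLQVNAGIGVLVVESCATKACKEVAARGVNARVRMRFM
LYKTPTKRNGDEGTKGIARNRSKRNSIMGI
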