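((CYAME,CYACA,(GALSU,GALPH)Galdieria)Cyanidiales,(PORPU,((PYRYE,PORUM)Bangiophyceae,(GRACH,CALTU,CHOCR)Florideophyceae)BangFlor)PBF)Rhodophyta;
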