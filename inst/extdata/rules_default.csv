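pattern,precedence,description
suspect_monoclonal,1,"sharpness high or light chain outside its interval in some zone"
polyclonal,2,"some immunoglobulin index high; sharpness and light chain normal in both zones"
hypogammaglobulinemia,3,"some immunoglobulin index low, none high; sharpness and light chain normal in both zones"
normal,4,"all ten indexes within their reference intervals"
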