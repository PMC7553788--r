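{"id":"s1","timestamp":"2020-03-01","source":"reddit_submission","title":"Lockdown megathread","body":"","score":0,"comment_count":3,"author_id":"u1"}
{"id":"s2","timestamp":"2020-03-02","source":"reddit_submission","title":"Case counts today","body":"","score":1,"comment_count":1,"author_id":"u2"}
{"id":"s3","timestamp":"2020-03-03","source":"reddit_submission","title":"Vaccine trial news","body":"","score":2,"comment_count":8,"author_id":"u3"}
{"id":"s4","timestamp":"2020-03-04","source":"reddit_submission","title":"Hospital capacity report","body":"","score":5,"comment_count":12,"author_id":"u4"}
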